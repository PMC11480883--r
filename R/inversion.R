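#' @keywords internal
tau_estimate <- function(tau_eff, estimator, lower = NA_real_, upper = NA_real_,
                         flag = NA_character_, rex_amplitude = NA_real_,
                         rex = NULL, details = NULL) {
  structure(list(tauEff = tau_eff, estimator = estimator,
                 lower = lower, upper = upper, flag = flag,
                 rexAmplitude = rex_amplitude, rex = rex, details = details),
            class = "tau_estimate")
}

#' @export
print.tau_estimate <- function(x, ...) {
  if (!is.na(x$flag) && x$flag == "non-physical") {
    cat(sprintf("tau_eff estimate (%s): non-physical (%.3g ns); treat as missing\n",
                x$estimator, x$tauEff * 1e9))
    return(invisible(x))
  }
  cat(sprintf("tau_eff = %.3f ns (%s estimator)", x$tauEff * 1e9, x$estimator))
  if (!is.na(x$lower) && !is.na(x$upper))
    cat(sprintf(" [feasible %.3f - %.3f ns]", x$lower * 1e9, x$upper * 1e9))
  if (!is.na(x$rexAmplitude))
    cat(sprintf("; Rex = Phi*omegaN^2, Phi = %.3g s (per-field Rex in $rex)",
                x$rexAmplitude))
  if (!is.na(x$flag)) cat(sprintf(" [flag: %s]", x$flag))
  cat("\n")
  invisible(x)
}

#' Linear-approximation coefficients for a field
#'
#' The exchange-free transverse rate decomposes into a term linear in
#' \eqn{\tau_{\mathrm{eff}}} plus Lorentzian terms that vanish for slow
#' dynamics:
#' \deqn{R_2^\circ = (4K_1 + 4K_2)\,\tau_{\mathrm{eff}} + \mathrm{Lorentzian\ terms},}
#' where \eqn{K_1 = d_{NH}^2/20} carries the dipolar \eqn{J(0)} contribution
#' and \eqn{K_2 = \Delta\sigma^2\omega_N^2/45} the CSA one. The
#' proportionality constant of the linear approximation is
#' \eqn{k = (4K_1 + 4K_2)^{-1}}, so \eqn{\tau_{\mathrm{eff}} \le k R_2^\circ}
#' always (Lorentzian terms are non-negative), with equality approached for
#' slow rotation.
#'
#' @param field a [field_settings()] object or proton frequency in MHz.
#' @param constants an [nmr_constants()] object.
#' @return Object of class `linear_coefficients`: list with `field`, `K1`,
#'   `K2` (s\eqn{^{-2}}), `k` (s\eqn{^2}), and the squared frequency
#'   combinations `A` \eqn{=(\omega_H-\omega_N)^2}, `B` \eqn{=\omega_N^2},
#'   `C` \eqn{=\omega_H^2}, `D` \eqn{=(\omega_H+\omega_N)^2} (rad\eqn{^2}/s\eqn{^2}).
#' @examples
#' linear_coefficients(500)$k * 1e9  # ~0.75
#' @export
linear_coefficients <- function(field, constants = nmr_constants()) {
  field <- as_field(field, constants)
  wH <- field$omegaH
  wN <- field$omegaN
  K1 <- constants$dNH^2 / 20
  K2 <- constants$deltaSigma^2 * wN^2 / 45
  k <- 1 / (4 * K1 + 4 * K2)
  structure(list(field = field, K1 = K1, K2 = K2, k = k,
                 A = (wH - wN)^2, B = wN^2, C = wH^2, D = (wH + wN)^2),
            class = "linear_coefficients")
}

#' @export
print.linear_coefficients <- function(x, ...) {
  cat(sprintf("Linear approximation at %.1f MHz: k = %.4f x 1e-9 s^2 (tau_eff = k * R2deg)\n",
              x$field$protonMHz, x$k * 1e9))
  invisible(x)
}

#' Linear-approximation estimate of tau_eff from R2
#'
#' \eqn{\tau_{\mathrm{eff}} = k R_2^\circ} with \eqn{k} from
#' [linear_coefficients()]. This is an exact upper bound on the effective
#' correlation time compatible with the observed rate; it overestimates for
#' fast dynamics (below roughly 3 ns) where the Lorentzian terms still
#' contribute.
#'
#' @param R2 exchange-free transverse rate \eqn{R_2^\circ} (s\eqn{^{-1}},
#'   non-negative). Any chemical exchange contribution must already be
#'   removed; see [tau_eff_rex_corrected()].
#' @param field a [field_settings()] object or proton frequency in MHz.
#' @param R2_err optional standard error on `R2`; propagated linearly
#'   (\eqn{\sigma_\tau = k\,\sigma_{R_2}}) into `details$tau_err`.
#' @param constants an [nmr_constants()] object.
#' @return a `tau_estimate` (estimator `"linear"`; `upper` equals the
#'   estimate itself).
#' @examples
#' tau_eff_linear(10, 300)  # 8.4 ns
#' @export
tau_eff_linear <- function(R2, field, R2_err = NULL, constants = nmr_constants()) {
  stopifnot(is.numeric(R2), length(R2) == 1L, is.finite(R2))
  if (R2 < 0) stop("R2 must be >= 0 (s^-1)", call. = FALSE)
  lc <- linear_coefficients(field, constants)
  tau <- lc$k * R2
  details <- if (!is.null(R2_err)) list(tau_err = lc$k * R2_err) else NULL
  tau_estimate(tau, "linear", upper = tau, details = details)
}

#' MD-calibrated fitted-line constants
#'
#' Per-field constants of the linear interpretation of \eqn{R_2^\circ}:
#' the theoretical proportionality constant `k` and the slope/intercept pair
#' `m` (\eqn{10^{-9}} s\eqn{^2}) and `c` (ns) of the empirical correction
#' \eqn{\tau_{\mathrm{eff}} = m R_2^\circ + c} calibrated against molecular
#' dynamics simulations, which compensates the systematic overestimation of
#' the plain linear approximation at short timescales. Defined only at the 15
#' tabulated spectrometer frequencies; no interpolation between fields is
#' offered because the calibration is per-field.
#'
#' @return data.frame with columns `protonMHz`, `k_1e9_s2`, `m_1e9_s2`,
#'   `c_ns`.
#' @examples
#' fitted_lines()
#' @export
fitted_lines <- function() {
  data.frame(
    protonMHz = c(300, 360, 400, 500, 600, 700, 720, 750, 800, 850, 900,
                  950, 1000, 1200, 1500),
    k_1e9_s2  = c(0.84, 0.81, 0.80, 0.75, 0.69, 0.64, 0.63, 0.61, 0.59,
                  0.56, 0.54, 0.51, 0.49, 0.41, 0.31),
    m_1e9_s2  = c(0.85, 0.83, 0.81, 0.76, 0.71, 0.65, 0.64, 0.62, 0.60,
                  0.57, 0.54, 0.52, 0.50, 0.41, 0.32),
    c_ns      = c(-1.52, -1.26, -1.11, -0.83, -0.64, -0.51, -0.49, -0.46,
                  -0.41, -0.38, -0.34, -0.31, -0.29, -0.22, -0.16)
  )
}

#' Fitted-line estimate of tau_eff from R2
#'
#' \eqn{\tau_{\mathrm{eff}} = m R_2^\circ + c} with the MD-calibrated
#' per-field constants of [fitted_lines()]. A result at or below zero is
#' returned flagged `"non-physical"` rather than clamped, so downstream
#' tables can show it as missing with a reason.
#'
#' @inheritParams tau_eff_linear
#' @param proton_mhz proton frequency in MHz; must be one of the 15
#'   tabulated fields (matched within 0.5 MHz).
#' @return a `tau_estimate` (estimator `"fitted"`).
#' @examples
#' tau_eff_fitted(10, 600)  # 6.46 ns
#' @export
tau_eff_fitted <- function(R2, proton_mhz) {
  stopifnot(is.numeric(R2), length(R2) == 1L, is.finite(R2))
  if (R2 < 0) stop("R2 must be >= 0 (s^-1)", call. = FALSE)
  tab <- fitted_lines()
  i <- which(abs(tab$protonMHz - proton_mhz) <= 0.5)
  if (length(i) != 1L)
    stop(sprintf(paste0("fitted-line constants are tabulated only at: %s MHz ",
                        "(got %.6g); use the linear or one-timescale estimator ",
                        "at other fields"),
                 paste(tab$protonMHz, collapse = ", "), proton_mhz),
         call. = FALSE)
  tau_ns <- tab$m_1e9_s2[i] * R2 + tab$c_ns[i]
  flag <- if (tau_ns <= 0) "non-physical" else NA_character_
  tau_estimate(tau_ns * 1e-9, "fitted", flag = flag)
}

# R2deg for a single-timescale model; cheap closed form used by the inverters.
r2_single_tau <- function(tau, field, constants = nmr_constants()) {
  vapply(tau, function(tt)
    relaxation_rates(sdm(1, tt), field, constants)$R2, numeric(1))
}

achievable_r2_range <- function(field, constants,
                                bracket = c(1e-13, 1e-6)) {
  c(r2_single_tau(bracket[1], field, constants),
    r2_single_tau(bracket[2], field, constants))
}

#' One-timescale estimate of tau_eff from R2
#'
#' Numerically inverts the exchange-free Redfield expression for
#' \eqn{R_2^\circ} under the assumption of a single rotational timescale:
#' returns the unique \eqn{\tau} with
#' \eqn{R_2^\circ(\tau) = R_2}, found by bracketed root search on
#' \eqn{[10^{-13}, 10^{-6}]} s (where \eqn{R_2^\circ(\tau)} is strictly
#' increasing). This estimator is the lower limit of the feasible
#' \eqn{\tau_{\mathrm{eff}}} range for fast dynamics and approaches the
#' linear approximation asymptotically for slow dynamics.
#'
#' @inheritParams tau_eff_linear
#' @param bracket search interval for \eqn{\tau} in seconds.
#' @return a `tau_estimate` (estimator `"one-timescale"`).
#' @examples
#' tau_eff_one_timescale(10, 600)
#' @export
tau_eff_one_timescale <- function(R2, field, constants = nmr_constants(),
                                  bracket = c(1e-13, 1e-6)) {
  stopifnot(is.numeric(R2), length(R2) == 1L, is.finite(R2))
  if (R2 <= 0) stop("R2 must be > 0 (s^-1)", call. = FALSE)
  field <- as_field(field, constants)
  rng <- achievable_r2_range(field, constants, bracket)
  if (R2 < rng[1] || R2 > rng[2])
    stop(sprintf(paste0("R2 = %.6g s^-1 is outside the achievable range ",
                        "[%.6g, %.6g] s^-1 for tau in [%.3g, %.3g] s at %.1f MHz"),
                 R2, rng[1], rng[2], bracket[1], bracket[2], field$protonMHz),
         call. = FALSE)
  # root search in log(tau): uniform relative resolution across 7 decades
  f <- function(lt) r2_single_tau(exp(lt), field, constants) - R2
  root <- stats::uniroot(f, lower = log(bracket[1]), upper = log(bracket[2]),
                         tol = 1e-14)
  tau <- exp(root$root)
  resid <- abs(r2_single_tau(tau, field, constants) - R2)
  if (resid > 1e-8 * R2)
    stop(sprintf("inversion did not converge: residual %.3g s^-1", resid),
         call. = FALSE)
  tau_estimate(tau, "one-timescale")
}

#' Feasible range of tau_eff for an observed R2
#'
#' For a given exchange-free \eqn{R_2^\circ}, the effective correlation times
#' achievable by any multi-exponential model form an interval: both
#' \eqn{R_2^\circ} and \eqn{\tau_{\mathrm{eff}}} are linear in the mixture
#' weights, so the feasible set of \eqn{(R_2^\circ, \tau_{\mathrm{eff}})}
#' pairs is the convex hull of the single-timescale curve
#' \eqn{\{(R_2^\circ(\tau), \tau)\}}. The upper boundary is the linear
#' approximation \eqn{k R_2^\circ}; the lower boundary is evaluated from the
#' lower convex hull of the curve sampled on a log-spaced grid. The lower
#' bound therefore carries a discretization error of order the squared grid
#' spacing (relative error below \eqn{10^{-4}} at the default grid), while
#' the upper bound is exact.
#'
#' @inheritParams tau_eff_one_timescale
#' @param n_grid number of log-spaced grid points (>= 500) on the bracket.
#' @return list with `lower` and `upper` bounds (s) and the `one_timescale`
#'   estimate for reference.
#' @examples
#' feasible_tau_bounds(10, 600)
#' @export
feasible_tau_bounds <- function(R2, field, constants = nmr_constants(),
                                bracket = c(1e-13, 1e-6), n_grid = 800) {
  stopifnot(n_grid >= 500)
  field <- as_field(field, constants)
  one_ts <- tau_eff_one_timescale(R2, field, constants, bracket)
  taus <- exp(seq(log(bracket[1]), log(bracket[2]), length.out = n_grid))
  x <- r2_single_tau(taus, field, constants)  # increasing in tau
  y <- taus
  # monotone-chain lower hull of (x, y); points already sorted by x
  hull <- integer(0)
  for (i in seq_along(x)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      cross <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      if (cross <= 0) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  lower <- stats::approx(x[hull], y[hull], xout = R2, rule = 1)$y
  upper <- linear_coefficients(field, constants)$k * R2
  list(lower = lower, upper = upper, one_timescale = one_ts$tauEff)
}

#' Chemical-exchange-corrected tau_eff from multi-field R2
#'
#' The chemical exchange contribution \eqn{R_{ex}} inflates measured
#' \eqn{R_2} and, in the fast-exchange limit, scales with the square of the
#' magnetic field: \eqn{R_{ex} = \Phi\,\omega_N^2}. Given \eqn{R_2} at two or
#' more distinct fields for one residue this solves
#' \deqn{\min_{\tau,\ \Phi \ge 0} \sum_f \left[R_2^{obs}(f) -
#'   R_2^\circ(\tau; f) - \Phi\,\omega_N(f)^2\right]^2}
#' with a single-timescale \eqn{R_2^\circ(\tau; f)}, making the recovered
#' \eqn{\tau_{\mathrm{eff}}} field-independent. \eqn{\Phi} is profiled out in
#' closed form at each \eqn{\tau} (linear least squares, clamped at zero) and
#' \eqn{\tau} is optimized on a log scale.
#'
#' @param R2 numeric vector of observed transverse rates (s\eqn{^{-1}}),
#'   one per field.
#' @param fields list of [field_settings()] objects or numeric vector of
#'   proton frequencies (MHz), same length as `R2`; at least two distinct
#'   fields (differing by more than 0.5 MHz).
#' @param constants an [nmr_constants()] object.
#' @param bracket search interval for \eqn{\tau} (s).
#' @return a `tau_estimate` (estimator `"rex-corrected"`) with
#'   `rexAmplitude` (\eqn{\Phi}, s) and per-field `rex` rates
#'   (s\eqn{^{-1}}, named by field). Flagged `"rex-pinned-zero"` when the
#'   unconstrained \eqn{\Phi} came out negative and was refit at zero.
#' @examples
#' f <- c(500, 600, 700)
#' r2 <- sapply(f, function(m) relaxation_rates(sdm(1, 5e-9), m)$R2) +
#'   2 * (sapply(f, function(m) field_settings(m)$omegaN) /
#'        field_settings(500)$omegaN)^2
#' tau_eff_rex_corrected(r2, f)
#' @export
tau_eff_rex_corrected <- function(R2, fields, constants = nmr_constants(),
                                  bracket = c(1e-13, 1e-6)) {
  stopifnot(is.numeric(R2), length(R2) >= 2L, all(is.finite(R2)))
  if (any(R2 <= 0)) stop("all R2 must be > 0 (s^-1)", call. = FALSE)
  if (is.numeric(fields)) fields <- lapply(fields, field_settings, constants = constants)
  if (length(fields) != length(R2))
    stop("`fields` and `R2` must have the same length", call. = FALSE)
  mhz <- vapply(fields, `[[`, numeric(1), "protonMHz")
  if (length(unique(round(mhz / 0.5))) < 2L)
    stop("Rex correction needs R2 at >= 2 distinct magnetic fields; got one",
         call. = FALSE)
  wN2 <- vapply(fields, `[[`, numeric(1), "omegaN")^2

  r2deg <- function(tau) vapply(fields, function(f)
    r2_single_tau(tau, f, constants), numeric(1))
  phi_hat <- function(resid) sum(resid * wN2) / sum(wN2 * wN2)
  ssr <- function(lt) {
    resid <- R2 - r2deg(exp(lt))
    phi <- max(0, phi_hat(resid))
    sum((resid - phi * wN2)^2)
  }
  opt <- stats::optimize(ssr, lower = log(bracket[1]), upper = log(bracket[2]),
                         tol = 1e-12)
  tau <- exp(opt$minimum)
  resid <- R2 - r2deg(tau)
  phi_raw <- phi_hat(resid)
  flag <- NA_character_
  if (phi_raw < 0) {
    # exchange cannot be negative: pin Phi = 0, tau reduces to a joint
    # one-timescale fit across fields
    flag <- "rex-pinned-zero"
    ssr0 <- function(lt) sum((R2 - r2deg(exp(lt)))^2)
    opt <- stats::optimize(ssr0, lower = log(bracket[1]),
                           upper = log(bracket[2]), tol = 1e-12)
    tau <- exp(opt$minimum)
    phi <- 0
  } else phi <- phi_raw
  rex <- phi * wN2
  names(rex) <- sprintf("%.6g", mhz)
  tau_estimate(tau, "rex-corrected", flag = flag, rex_amplitude = phi,
               rex = rex, details = list(ssr = ssr(log(tau))))
}
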