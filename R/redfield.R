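#' Forward Redfield calculator: R1, R2 (exchange-free) and hetNOE
#'
#' Maps a spectral-density model of N-H bond rotation to the \eqn{^{15}}N
#' relaxation observables at a given magnetic field. With
#' \eqn{d \equiv d_{NH}} the dipolar coupling constant, \eqn{\Delta\sigma} the
#' \eqn{^{15}}N chemical shift anisotropy and \eqn{J} evaluated per
#' [spectral_density()]:
#' \deqn{R_1 = \frac{d^2}{40}\left[J(\omega_H-\omega_N) + 3J(\omega_N) +
#'   6J(\omega_H+\omega_N)\right] + \frac{\Delta\sigma^2\omega_N^2}{15} J(\omega_N)}
#' \deqn{R_2^\circ = \frac{d^2}{40}\left[4J(0) + J(\omega_H-\omega_N) +
#'   3J(\omega_N) + 6J(\omega_H) + 6J(\omega_H+\omega_N)\right] +
#'   \frac{\Delta\sigma^2\omega_N^2}{90}\left[4J(0) + 3J(\omega_N)\right]}
#' \deqn{\mathrm{hetNOE} = 1 + \frac{\gamma_H}{\gamma_N}\frac{d^2}{40}
#'   \frac{6J(\omega_H+\omega_N) - J(\omega_H-\omega_N)}{R_1}}
#'
#' \eqn{R_2^\circ} is the transverse rate without the chemical exchange
#' contribution (\eqn{R_2^\circ = R_2 - R_{ex}}); one proton per N-H bond is
#' assumed. The dipolar/CSA prefactor convention is tied to the
#' \eqn{J(0) = 2\tau_{\mathrm{eff}}} normalization and reproduces the
#' per-field proportionality constants of [linear_coefficients()].
#'
#' @param model an [sdm()] object.
#' @param field a [field_settings()] object, or a proton frequency in MHz.
#' @param constants an [nmr_constants()] object; pass
#'   `nmr_constants(delta_sigma = 0)` for dipolar-only rates.
#' @return An object of class `relaxation_rates`: list with `R1`, `R2`
#'   (both s\eqn{^{-1}}; `R2` is \eqn{R_2^\circ}), `hetNOE` (dimensionless)
#'   and `field`.
#' @examples
#' relaxation_rates(sdm(1, 5e-9), field_settings(600))
#' @export
relaxation_rates <- function(model, field, constants = nmr_constants()) {
  stopifnot(inherits(model, "sdm"))
  field <- as_field(field, constants)
  wH <- field$omegaH
  wN <- field$omegaN
  d2 <- constants$dNH^2
  csa2 <- constants$deltaSigma^2 * wN^2

  J0   <- spectral_density(model, 0)
  JmHN <- spectral_density(model, wH - wN)
  JN   <- spectral_density(model, wN)
  JH   <- spectral_density(model, wH)
  JpHN <- spectral_density(model, wH + wN)

  R1 <- (d2 / 40) * (JmHN + 3 * JN + 6 * JpHN) + (csa2 / 15) * JN
  R2 <- (d2 / 40) * (4 * J0 + JmHN + 3 * JN + 6 * JH + 6 * JpHN) +
        (csa2 / 90) * (4 * J0 + 3 * JN)
  hetNOE <- 1 + (constants$gammaH / constants$gammaN) *
    (d2 / 40) * (6 * JpHN - JmHN) / R1

  structure(list(R1 = R1, R2 = R2, hetNOE = hetNOE, field = field),
            class = "relaxation_rates")
}

#' @export
print.relaxation_rates <- function(x, ...) {
  cat(sprintf("15N relaxation at %.1f MHz: R1 = %.4g 1/s, R2deg = %.4g 1/s, hetNOE = %.4g\n",
              x$field$protonMHz, x$R1, x$R2, x$hetNOE))
  invisible(x)
}
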