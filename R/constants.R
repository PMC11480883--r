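#' Physical constants for 15N amide relaxation
#'
#' Returns the set of physical constants entering the Redfield expressions for
#' backbone amide \eqn{^{15}}N relaxation: CODATA gyromagnetic ratios, the
#' vacuum permeability and reduced Planck constant, the \eqn{^{15}}N chemical
#' shift anisotropy and the effective N-H bond length. The dipolar coupling
#' constant \eqn{d_{NH} = (\mu_0/4\pi)\,\hbar\,\gamma_H |\gamma_N| / \langle
#' r_{NH}^3 \rangle} is derived from the others.
#'
#' @param delta_sigma chemical shift anisotropy of the amide \eqn{^{15}}N,
#'   dimensionless (default \eqn{-160} ppm, i.e. \code{-160e-6}). Set to 0 to
#'   switch the CSA relaxation mechanism off (dipolar-only rates).
#' @param r_nh effective N-H bond length in metres (default 1.01 Angstrom).
#'
#' @return An object of class `nmr_constants`: a list with elements
#'   `mu0` (T m/A), `hbar` (J s), `gammaH`, `gammaN` (rad s\eqn{^{-1}}
#'   T\eqn{^{-1}}; `gammaN` is negative), `deltaSigma` (dimensionless),
#'   `rNH_cubed` (m\eqn{^3}) and the derived `dNH` (rad/s).
#' @examples
#' cst <- nmr_constants()
#' cst$dNH
#' @export
nmr_constants <- function(delta_sigma = -160e-6, r_nh = 1.01e-10) {
  stopifnot(is.numeric(delta_sigma), length(delta_sigma) == 1L, is.finite(delta_sigma),
            is.numeric(r_nh), length(r_nh) == 1L, r_nh > 0)
  mu0 <- 4 * pi * 1e-7
  hbar <- 1.054571817e-34
  gammaH <- 2.6752218744e8
  gammaN <- -2.7126180436e7
  rNH_cubed <- r_nh^3
  dNH <- (mu0 / (4 * pi)) * hbar * gammaH * abs(gammaN) / rNH_cubed
  structure(
    list(mu0 = mu0, hbar = hbar, gammaH = gammaH, gammaN = gammaN,
         deltaSigma = delta_sigma, rNH_cubed = rNH_cubed, dNH = dNH),
    class = "nmr_constants"
  )
}

#' @export
print.nmr_constants <- function(x, ...) {
  cat("15N amide relaxation constants\n")
  cat(sprintf("  gammaH     %.10e rad/s/T\n", x$gammaH))
  cat(sprintf("  gammaN     %.10e rad/s/T\n", x$gammaN))
  cat(sprintf("  deltaSigma %.1f ppm\n", x$deltaSigma * 1e6))
  cat(sprintf("  r_NH       %.3f Angstrom (effective)\n", x$rNH_cubed^(1 / 3) * 1e10))
  cat(sprintf("  d_NH       %.4f rad/s\n", x$dNH))
  invisible(x)
}

#' Magnetic field settings from the proton Larmor frequency
#'
#' NMR magnetic field strengths are conventionally quoted as the \eqn{^{1}}H
#' Larmor frequency in MHz. This converts that figure into the angular
#' frequencies of \eqn{^{1}}H and \eqn{^{15}}N needed by the Redfield
#' expressions: \eqn{\omega_H = 2\pi \nu_H \times 10^6} and
#' \eqn{\omega_N = \omega_H |\gamma_N| / \gamma_H}.
#'
#' @param proton_mhz proton Larmor frequency in MHz (positive scalar).
#' @param constants an [nmr_constants()] object supplying the gyromagnetic
#'   ratios.
#' @return An object of class `field_settings` with elements `protonMHz`,
#'   `omegaH` and `omegaN` (both rad/s; `omegaN` is the magnitude).
#' @examples
#' f <- field_settings(600)
#' f$omegaH / (2 * pi * 1e6)  # back to MHz
#' @export
field_settings <- function(proton_mhz, constants = nmr_constants()) {
  if (!is.numeric(proton_mhz) || length(proton_mhz) != 1L ||
      !is.finite(proton_mhz) || proton_mhz <= 0) {
    stop("`proton_mhz` must be a single positive finite number (MHz)", call. = FALSE)
  }
  omegaH <- 2 * pi * proton_mhz * 1e6
  omegaN <- omegaH * abs(constants$gammaN) / constants$gammaH
  structure(
    list(protonMHz = proton_mhz, omegaH = omegaH, omegaN = omegaN,
         constants = constants),
    class = "field_settings"
  )
}

#' @export
print.field_settings <- function(x, ...) {
  cat(sprintf("Field: %.1f MHz (1H); omegaH = %.4e rad/s, omegaN = %.4e rad/s\n",
              x$protonMHz, x$omegaH, x$omegaN))
  invisible(x)
}

as_field <- function(field, constants = nmr_constants()) {
  if (inherits(field, "field_settings")) return(field)
  field_settings(field, constants)
}
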