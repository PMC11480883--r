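# Independent numerical oracles, deliberately avoiding the package's own
# Lorentzian closed form for J(omega).

# g(t) for a multi-exponential model, direct evaluation
g_of_t <- function(weights, timescales, t) {
  drop(exp(-outer(t, 1 / timescales)) %*% weights)
}

# J(omega) = 2 * integral_0^inf g(t) cos(omega t) dt by composite Simpson
# quadrature on a grid resolving both the decay and the oscillation
J_quadrature <- function(weights, timescales, omega) {
  Tmax <- 40 * max(timescales)
  # resolve both the fastest decay component and the oscillation
  n_decay <- max(4000, ceiling(Tmax / (min(timescales) / 20)))
  n_osc <- if (omega > 0) ceiling(Tmax * omega / (2 * pi)) * 40 else 0
  n <- max(n_decay, n_osc)
  if (n %% 2 == 1) n <- n + 1
  h <- Tmax / n
  # composite Simpson accumulated in chunks to bound memory at large n
  total <- 0
  chunk <- 2e6L
  i0 <- 0L
  while (i0 < n) {
    i1 <- min(i0 + chunk, n)
    idx <- i0:i1
    t <- idx * h
    f <- g_of_t(weights, timescales, t) * cos(omega * t)
    w <- ifelse(idx %% 2 == 1, 4, 2)
    w[idx == 0] <- 1
    w[idx == n] <- 1
    if (i0 > 0) w[1] <- 0  # shared endpoint already counted
    total <- total + sum(w * f)
    i0 <- i1
  }
  2 * h / 3 * total
}

# brute-force R2deg from quadrature J values, dipolar + CSA prefactors
r2_oracle <- function(weights, timescales, proton_mhz) {
  cst <- taueff::nmr_constants()
  wH <- 2 * pi * proton_mhz * 1e6
  wN <- wH * abs(cst$gammaN) / cst$gammaH
  Jq <- function(w) J_quadrature(weights, timescales, w)
  (cst$dNH^2 / 40) * (4 * Jq(0) + Jq(wH - wN) + 3 * Jq(wN) + 6 * Jq(wH) +
                        6 * Jq(wH + wN)) +
    (cst$deltaSigma^2 * wN^2 / 90) * (4 * Jq(0) + 3 * Jq(wN))
}

# random normalized mixture model (for property tests)
random_sdm <- function(max_components = 8, tau_range = c(1e-12, 2e-7)) {
  n <- sample(1:max_components, 1)
  w <- stats::runif(n)
  taueff::sdm(w / sum(w),
              exp(stats::runif(n, log(tau_range[1]), log(tau_range[2]))))
}

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "taueff")
  if (p == "") p <- file.path("..", "..", "inst", "extdata", name)
  p
}
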