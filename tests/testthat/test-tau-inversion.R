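test_that("proportionality constants reproduce the tabulated k at every field", {
  tab <- fitted_lines()
  for (i in seq_len(nrow(tab))) {
    k <- linear_coefficients(tab$protonMHz[i])$k * 1e9
    # rounded to the table's 2 decimals, agreement within +/- 0.01 absolute
    expect_lte(abs(round(k, 2) - tab$k_1e9_s2[i]), 0.01 + 1e-9,
               label = sprintf("|k - table| at %g MHz", tab$protonMHz[i]))
  }
  lc <- linear_coefficients(500)
  expect_equal(lc$k * (4 * lc$K1 + 4 * lc$K2), 1, tolerance = 1e-12)
  expect_gt(lc$K1, 0); expect_gt(lc$K2, 0)
  f <- lc$field
  expect_equal(lc$A, (f$omegaH - f$omegaN)^2)
  expect_equal(lc$B, f$omegaN^2)
  expect_equal(lc$C, f$omegaH^2)
  expect_equal(lc$D, (f$omegaH + f$omegaN)^2)
})

test_that("linear estimator is k*R2 with error propagation", {
  expect_equal(tau_eff_linear(10, 300)$tauEff * 1e9, 8.4, tolerance = 0.05)
  expect_equal(tau_eff_linear(10, 1500)$tauEff * 1e9, 3.1, tolerance = 0.05)
  expect_equal(tau_eff_linear(0, 600)$tauEff, 0)
  est <- tau_eff_linear(10, 600, R2_err = 0.5)
  expect_equal(est$details$tau_err, linear_coefficients(600)$k * 0.5)
  expect_equal(est$upper, est$tauEff)  # the linear estimate IS the upper bound
  expect_error(tau_eff_linear(-1, 600), ">= 0")
})

test_that("fitted-line estimator uses tabulated m, c and flags non-physical", {
  expect_equal(tau_eff_fitted(10, 600)$tauEff * 1e9, 6.46)
  expect_equal(tau_eff_fitted(10, 300)$tauEff * 1e9, 6.98)
  low <- tau_eff_fitted(0.1, 600)
  expect_equal(low$flag, "non-physical")
  # never clamped: the raw (negative) value is retained for inspection
  expect_lt(low$tauEff, 0)
  expect_error(tau_eff_fitted(10, 650), "tabulated")
})

test_that("one-timescale inversion round-trips the forward model", {
  taus <- c(1e-11, 1e-10, 1e-9, 5e-9, 2e-8, 1e-7, 5e-7)
  for (mhz in fitted_lines()$protonMHz) {
    for (tt in taus) {
      r2 <- relaxation_rates(sdm(1, tt), mhz)$R2
      expect_equal(tau_eff_one_timescale(r2, mhz)$tauEff, tt,
                   tolerance = 1e-6,
                   label = sprintf("tau=%.3g at %g MHz", tt, mhz))
    }
  }
})

test_that("one-timescale never exceeds linear and converges to it for slow rotation", {
  for (r2 in c(0.5, 2, 10, 40)) {
    expect_lte(tau_eff_one_timescale(r2, 600)$tauEff,
               tau_eff_linear(r2, 600)$tauEff)
  }
  r2_slow <- relaxation_rates(sdm(1, 50e-9), 600)$R2
  one <- tau_eff_one_timescale(r2_slow, 600)$tauEff
  lin <- tau_eff_linear(r2_slow, 600)$tauEff
  expect_equal(one, lin, tolerance = 0.02)
  # at 3 ns the nonlinear terms still matter: deviation is material
  r2_fast <- relaxation_rates(sdm(1, 3e-9), 600)$R2
  dev <- tau_eff_linear(r2_fast, 600)$tauEff /
    tau_eff_one_timescale(r2_fast, 600)$tauEff - 1
  expect_gt(dev, 0.05)
})

test_that("inversion rejects rates outside the achievable range", {
  err <- expect_error(tau_eff_one_timescale(1e6, 600), "achievable range")
  expect_match(conditionMessage(err), "600.0 MHz")
  expect_error(tau_eff_one_timescale(0, 600), "> 0")
})

test_that("single-field estimators are non-decreasing in R2", {
  r2s <- seq(0.5, 40, length.out = 40)
  for (fn in list(function(r) tau_eff_linear(r, 500)$tauEff,
                  function(r) tau_eff_fitted(r, 500)$tauEff,
                  function(r) tau_eff_one_timescale(r, 500)$tauEff)) {
    expect_true(all(diff(vapply(r2s, fn, numeric(1))) >= 0))
  }
})

test_that("field invariance: exchange-free estimates agree across fields", {
  for (tt in c(1e-9, 5e-9, 2e-8)) {
    t500 <- tau_eff_one_timescale(relaxation_rates(sdm(1, tt), 500)$R2, 500)
    t850 <- tau_eff_one_timescale(relaxation_rates(sdm(1, tt), 850)$R2, 850)
    expect_equal(t500$tauEff, t850$tauEff, tolerance = 1e-6)
  }
})

test_that("feasible bounds bracket every achievable mixture", {
  b <- feasible_tau_bounds(10, 600)
  expect_lte(b$lower, b$one_timescale)
  expect_lte(b$one_timescale, b$upper)
  # Monte-Carlo containment: random 5-component mixtures land inside the hull
  set.seed(202)
  k600 <- linear_coefficients(600)$k
  for (rep in 1:1000) {
    m <- random_sdm(5, c(1e-12, 1e-7))
    r2 <- relaxation_rates(m, 600)$R2
    te <- tau_eff(m)
    expect_lte(te, k600 * r2)                     # upper bound, exact
    bb <- feasible_tau_bounds(r2, 600, n_grid = 500)
    # lower boundary is a chord interpolation on a finite grid: containment
    # holds up to the O(grid-spacing^2) discretization of the hull
    expect_gte(te, bb$lower * (1 - 1e-3))
    expect_lte(te, bb$upper * (1 + 1e-12))
  }
})

test_that("Rex correction recovers tau and exchange from multi-field data", {
  fields <- c(500, 600, 700)
  wN2 <- vapply(fields, function(m) field_settings(m)$omegaN^2, numeric(1))
  r2_clean <- vapply(fields, function(m) relaxation_rates(sdm(1, 5e-9), m)$R2,
                     numeric(1))
  # Rex = 2 s^-1 at 500 MHz, scaled as omegaN^2 to the other fields
  r2_obs <- r2_clean + 2.0 * wN2 / wN2[1]
  est <- tau_eff_rex_corrected(r2_obs, fields)
  expect_equal(est$tauEff, 5e-9, tolerance = 1e-4)
  expect_equal(unname(est$rex[1]), 2.0, tolerance = 1e-4)
  expect_true(is.na(est$flag))
})

test_that("Rex fit degenerates gracefully without exchange", {
  fields <- c(500, 850)
  r2 <- vapply(fields, function(m) relaxation_rates(sdm(1, 4e-9), m)$R2,
               numeric(1))
  est <- tau_eff_rex_corrected(r2, fields)
  one <- tau_eff_one_timescale(r2[1], 500)
  expect_equal(est$tauEff, one$tauEff, tolerance = 1e-6)
  expect_lte(est$rexAmplitude, 1e-12 * max(r2))
  # apparent negative exchange is pinned to zero and flagged
  est2 <- tau_eff_rex_corrected(r2 - c(0, 0.5), fields)
  expect_equal(est2$flag, "rex-pinned-zero")
  expect_equal(est2$rexAmplitude, 0)
  expect_error(tau_eff_rex_corrected(r2[1], 500), "length")
  expect_error(tau_eff_rex_corrected(c(10, 11), c(600, 600.2)), "distinct")
})

test_that("Rex recovery under noise tracks the information limit of the design", {
  fields <- c(500, 600, 700)
  wN2 <- vapply(fields, function(m) field_settings(m)$omegaN^2, numeric(1))
  tau0 <- 5e-9
  r2_obs <- vapply(fields, function(m) relaxation_rates(sdm(1, tau0), m)$R2,
                   numeric(1)) + 2.0 * wN2 / wN2[1]
  # linearized least-squares covariance for (tau, Phi) under 2% relative
  # noise: an independent yardstick for what any estimator can achieve
  eps <- 1e-13
  a <- (vapply(fields, function(m)
    relaxation_rates(sdm(1, tau0 + eps), m)$R2, numeric(1)) -
      vapply(fields, function(m)
        relaxation_rates(sdm(1, tau0), m)$R2, numeric(1))) / eps
  A <- cbind(a * 1e-9, wN2 / wN2[1])
  S <- diag((0.02 * r2_obs)^2)
  AtAinv <- solve(crossprod(A))
  sd_tau_rel <- sqrt((AtAinv %*% t(A) %*% S %*% A %*% AtAinv)[1, 1]) / (tau0 * 1e9)
  median_bound <- stats::qnorm(0.75) * sd_tau_rel  # half-normal median

  set.seed(77)
  errs <- replicate(100, {
    r2 <- r2_obs * (1 + stats::rnorm(3, sd = 0.02))
    abs(tau_eff_rex_corrected(r2, fields)$tauEff - tau0) / tau0
  })
  # the solver adds no material error on top of the noise floor
  expect_lt(stats::median(errs), 1.25 * median_bound)
})
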