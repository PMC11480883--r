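test_that("trajectory and correlation-function containers validate input", {
  expect_error(vector_trajectory(matrix(c(1, 0, 0), 1, 3), 1e-11), "n >= 2")
  expect_error(vector_trajectory(rbind(c(1, 0, 0), c(2, 0, 0)), 1e-11),
               "unit-norm")
  expect_error(correlation_function(c(0, 1e-9), c(0.9, 0.5)), "g\\(0\\)")
  expect_error(correlation_function(c(1e-9, 0), c(1, 0.5)), "start at 0")
})

test_that("P2 autocorrelation of a constant vector is identically 1", {
  u <- matrix(rep(c(0, 0.6, 0.8), each = 50), 50, 3)
  g <- p2_autocorrelation(vector_trajectory(u, 1e-12), 20)
  expect_equal(g$values, rep(1, 21), tolerance = 1e-9)
})

test_that("P2 autocorrelation of independent random orientations vanishes", {
  set.seed(5)
  n <- 8000
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2))
  g <- p2_autocorrelation(vector_trajectory(v, 1e-12), 50)
  expect_equal(g$values[1], 1)
  expect_lt(max(abs(g$values[-1])), 0.05)  # E[P2] over the sphere is 0
})

test_that("FFT estimator equals the direct sliding-window average", {
  set.seed(9)
  v <- matrix(stats::rnorm(3 * 200), 200, 3)
  v <- v / sqrt(rowSums(v^2))
  tr <- vector_trajectory(v, 1e-12)
  g <- p2_autocorrelation(tr, 30)
  p2 <- function(x) (3 * x^2 - 1) / 2
  direct <- vapply(0:30, function(k) {
    idx <- seq_len(200 - k)
    mean(p2(rowSums(v[idx, , drop = FALSE] * v[idx + k, , drop = FALSE])))
  }, numeric(1))
  expect_equal(g$values, direct, tolerance = 1e-9)
})

test_that("rotational diffusion is deterministic, unit-norm, and decays as exp(-6 Dr t)", {
  tr1 <- simulate_rotational_diffusion(1e8, 1e-11, 5000, seed = 31)
  tr2 <- simulate_rotational_diffusion(1e8, 1e-11, 5000, seed = 31)
  expect_identical(tr1$vectors, tr2$vectors)
  expect_lt(max(abs(sqrt(rowSums(tr1$vectors^2)) - 1)), 1e-6)
  expect_error(simulate_rotational_diffusion(1e10, 1e-11, 100), "small-step")

  tr <- simulate_rotational_diffusion(1e8, 1e-11, 2e5, seed = 101)
  g <- p2_autocorrelation(tr, 3000)
  # pointwise closed form over the first two decay times
  sel <- g$lags <= 2 / (6 * 1e8)
  expect_lt(max(abs(g$values[sel] - exp(-6 * 1e8 * g$lags[sel]))), 0.03)
  # fitted single-exponential decay time ~ 1/(6 Dr) within 5%
  fitsel <- g$values > 0.05
  slope <- unname(stats::coef(stats::lm(log(g$values[fitsel]) ~ g$lags[fitsel]))[2])
  expect_equal(-1 / slope, 1 / (6 * 1e8), tolerance = 0.05)
})

test_that("multi-exponential NNLS fit recovers tau_eff", {
  lags <- seq(0, 50e-9, by = 2e-11)
  # two-component decay: individual components are not identifiable on the
  # grid but their weighted timescale sum is
  g2 <- correlation_function(lags, g_of_t(c(0.7, 0.3), c(0.5e-9, 8e-9), lags))
  fit2 <- fit_multiexponential(g2)
  expect_equal(tau_eff(fit2$model), 2.75e-9, tolerance = 0.02)
  # off-grid true timescales: fit quality limited by the 64-point grid
  expect_equal(fit2$g0, 1, tolerance = 5e-3)
  expect_lt(fit2$residual, 1e-3)

  g1 <- correlation_function(lags, exp(-lags / 3e-9))
  expect_equal(tau_eff(fit_multiexponential(g1)$model), 3e-9, tolerance = 0.01)

  gstatic <- correlation_function(seq(0, 1e-8, by = 1e-10),
                                  rep(1, 101))
  fs <- fit_multiexponential(gstatic)
  expect_equal(fs$flag, "non-decaying")
  expect_gt(max(fs$model$timescales[fs$model$weights > 0.5]), 1e-8)
})

test_that("ACF integration matches closed forms with and without tail", {
  lags <- seq(0, 20e-9, by = 2e-11)  # 10 decay times of a 2 ns exponential
  g <- correlation_function(lags, exp(-lags / 2e-9))
  with_tail <- tau_eff_from_acf(g, "exponential")
  expect_equal(as.numeric(with_tail), 2e-9, tolerance = 0.01)
  expect_true(is.na(attr(with_tail, "flag")))
  truncated <- tau_eff_from_acf(g, "truncate")
  expect_equal(as.numeric(truncated), (1 - exp(-10)) * 2e-9, tolerance = 1e-3)

  gdeg <- correlation_function(c(0, 1e-11, 2e-11), c(1, 0, 0))
  deg <- tau_eff_from_acf(gdeg)
  expect_equal(as.numeric(deg), 1e-11 / 2)  # half the first trapezoid
  expect_equal(attr(deg, "flag"), "degenerate")

  gflat <- correlation_function(seq(0, 1e-9, by = 1e-11), rep(1, 101))
  expect_equal(attr(tau_eff_from_acf(gflat, "exponential"), "flag"),
               "non-decaying-tail")
})

test_that("grid fit and direct integration agree on synthetic fixtures", {
  lags <- seq(0, 60e-9, by = 5e-11)
  set.seed(404)
  for (rep in 1:5) {
    m <- random_sdm(4, c(1e-10, 1e-8))
    g <- correlation_function(lags, g_of_t(m$weights, m$timescales, lags))
    t_fit <- tau_eff(fit_multiexponential(g)$model)
    t_int <- as.numeric(tau_eff_from_acf(g, "exponential"))
    expect_equal(t_fit, t_int, tolerance = 0.05)
    expect_equal(t_fit, tau_eff(m), tolerance = 0.05)
  }
})

test_that("trajectory and correlation CSV round trips preserve data", {
  tr <- simulate_rotational_diffusion(5e7, 1e-11, 200, seed = 3)
  path <- tempfile(fileext = ".csv")
  df <- data.frame(t = (0:199) * 1e-11, x = tr$vectors[, 1],
                   y = tr$vectors[, 2], z = tr$vectors[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  tr2 <- read_vector_trajectory(path)
  expect_equal(tr2$vectors, tr$vectors, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(tr2$timestep, 1e-11)

  g <- p2_autocorrelation(tr, 50)
  gpath <- tempfile(fileext = ".csv")
  write_correlation_csv(g, gpath)
  g2 <- read_correlation_csv(gpath)
  expect_equal(g2$values, g$values, tolerance = 1e-12)
})
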