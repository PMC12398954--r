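test_that("TSR counts strict-threshold successes as percentages", {
  x <- rep(0, 10)
  expect_true(all(tsr(x, x) == 100))
  y <- x; y[4] <- 1.5   # one deviation of exactly 1.5 mm
  out <- tsr(y, x, c(1, 1.5, 2))
  expect_equal(unname(out), c(90, 90, 100))
  expect_error(tsr(numeric(0), numeric(0)), "empty")
  expect_error(tsr(1:3, 1:2), "equal length")
  expect_error(tsr(1:3, 1:3, c(-1)), "positive")
})

test_that("TSR matches the analytic Gaussian expression", {
  set.seed(31)
  n <- 1e5
  sigma <- 0.5
  dev <- rnorm(n, 0, sigma)
  got <- tsr(dev, rep(0, n), 1)[[1]]
  expected <- 100 * (2 * pnorm(1 / sigma) - 1)   # 95.45%
  se <- 100 * sqrt(expected / 100 * (1 - expected / 100) / n)
  expect_lt(abs(got - expected), 3 * se)
  # monotone non-decreasing in the threshold
  taus <- c(0.25, 0.5, 1, 2, 5)
  expect_true(all(diff(tsr(dev, rep(0, n), taus)) >= 0))
  expect_equal(tsr(dev, rep(0, n), 1e9)[[1]], 100)
})

test_that("MAE behaves as the half-normal mean under Gaussian errors", {
  expect_equal(mae(1:5, 1:5), 0)
  expect_equal(mae(c(1, -1), c(0, 0)), 1)
  set.seed(8)
  n <- 1e5
  sigma <- 0.61
  d <- rnorm(n, 0, sigma)
  expected <- sigma * sqrt(2 / pi)
  se <- sigma * sqrt(1 - 2 / pi) / sqrt(n)
  expect_lt(abs(mae(d, rep(0, n)) - expected), 3 * se)
  # MAE >= |bias| always
  expect_gte(mae(d + 0.3, rep(0, n)), abs(mean(d + 0.3)))
})

test_that("Pearson correlation honours affine invariance and noise theory", {
  a <- sin(seq(0, 10, by = 0.01))
  expect_equal(pearson_r(a, 2 * a + 3), 1)
  expect_equal(pearson_r(a, -a), -1)
  b <- a + rnorm(length(a), 0, 0.2)
  expect_equal(pearson_r(a, b), pearson_r(5 * a - 2, 0.1 * b + 7))
  expect_error(pearson_r(rep(1, 10), 1:10), "constant")
  expect_error(pearson_r(1:2, 1:2), "3")

  # sinusoid amplitude A with additive N(0, sigma^2):
  # r -> (1 + sigma^2 / (A^2/2))^(-1/2)
  set.seed(12)
  t <- seq(0, 100, length.out = 1000)
  clean <- 10 * sin(2 * pi * 0.2 * t)
  noisy <- clean + rnorm(1000, 0, 0.61)
  expected <- 1 / sqrt(1 + 0.61^2 / (10^2 / 2))
  expect_lt(abs(pearson_r(noisy, clean) - expected), 0.002)
})

test_that("Bland-Altman reproduces the limits-of-agreement formula", {
  a <- c(1, 2, 3, 4)
  ba0 <- bland_altman(a, a)
  expect_equal(ba0$bias_mm, 0)
  expect_equal(ba0$sd_mm, 0)
  expect_equal(c(ba0$loa_upper_mm, ba0$loa_lower_mm), c(0, 0))
  # antisymmetry
  b <- a + c(0.1, -0.2, 0.3, 0)
  expect_equal(bland_altman(a, b)$bias_mm, -bland_altman(b, a)$bias_mm)
  expect_equal(bland_altman(a, b)$sd_mm, bland_altman(b, a)$sd_mm)
  expect_error(bland_altman(1, 1), "2")

  set.seed(21)
  d <- rnorm(1e4, -0.01, 0.35)
  ba <- bland_altman(d, rep(0, 1e4))
  expect_lt(abs(ba$bias_mm - (-0.01)), 3 * 0.35 / sqrt(1e4))
  expect_lt(abs(ba$loa_upper_mm - 0.676), 0.03)
  expect_lt(abs(ba$loa_lower_mm - (-0.696)), 0.03)
})

test_that("limits of agreement reproduce the published agreement table", {
  expect_equal(limits_of_agreement(0, 1), c(upper = 1.96, lower = -1.96))
  expect_error(limits_of_agreement(0, -1), "sd")
  # printed bias/SD pairs (vertical and longitudinal, five depths) against
  # their printed limits; printed values carry two-decimal rounding
  rows <- list(
    list(bias = -0.01, sd = 0.35, lim = c(0.67, -0.70), tol = 0.02),
    list(bias = 0.02, sd = 0.32, lim = c(0.66, -0.61), tol = 0.02),
    list(bias = -0.02, sd = 0.52, lim = c(1.00, -1.05), tol = 0.02),
    list(bias = 0.00, sd = 0.60, lim = c(1.19, -1.18), tol = 0.02),
    list(bias = -0.03, sd = 0.68, lim = c(1.29, -1.35), tol = 0.02),
    list(bias = -0.03, sd = 0.48, lim = c(0.91, -0.98), tol = 0.02),
    list(bias = -0.05, sd = 0.55, lim = c(1.04, -1.13), tol = 0.02),
    # this row's printed SD is rounded inconsistently with its printed
    # limits; the formula still lands within one rounding step further out
    list(bias = -0.03, sd = 1.00, lim = c(1.98, -2.03), tol = 0.05),
    list(bias = 0.06, sd = 1.42, lim = c(2.83, -2.72), tol = 0.02),
    list(bias = 0.00, sd = 2.11, lim = c(4.13, -4.13), tol = 0.02)
  )
  for (r in rows) {
    loa <- limits_of_agreement(r$bias, r$sd)
    expect_lt(max(abs(unname(loa) - r$lim)), r$tol + 1e-9)
  }
})

test_that("trace alignment finds and removes a constructed delay", {
  t <- seq(0, 30, by = 0.1)
  y <- 10 * sin(2 * pi * 0.2 * t)
  a <- data.frame(t_s = t, y_vert_mm = y)
  al0 <- align_traces(a, a)
  expect_equal(al0$applied_shift_s, 0)
  expect_equal(al0$a, al0$b)
  # b is a delayed by 0.2 s
  b <- data.frame(t_s = t, y_vert_mm = 10 * sin(2 * pi * 0.2 * (t - 0.2)))
  al <- align_traces(a, b, max_shift_s = 0.5)
  expect_lt(abs(al$applied_shift_s - 0.2), 0.005)
  expect_lt(mae(al$a, al$b), 0.05)
  far <- data.frame(t_s = t + 1000, y_vert_mm = y)
  expect_error(align_traces(a, far), "overlap")
})

test_that("phase-shift latency recovers injected delays within 1 ms", {
  tref <- seq(0, 20, by = 0.001)   # 1 kHz reference
  tmea <- seq(0, 20, by = 0.1)     # 10 Hz measured
  for (delay_ms in c(0, 60, 100, 250, 480)) {
    ref <- data.frame(t_s = tref, y_vert_mm = 10 * sin(2 * pi * 0.25 * tref))
    mea <- data.frame(t_s = tmea,
                      y_vert_mm = 10 * sin(2 * pi * 0.25 * (tmea - delay_ms / 1000)))
    est <- estimate_latency(ref, mea)
    expect_lt(abs(est$latency_ms - delay_ms), 1)
    expect_gte(est$uncertainty_ms, 0)
  }
  # half-period delay outside the window is flagged, not aliased
  mea2 <- data.frame(t_s = tmea,
                     y_vert_mm = 10 * sin(2 * pi * 0.25 * (tmea - 2)))
  ref <- data.frame(t_s = tref, y_vert_mm = 10 * sin(2 * pi * 0.25 * tref))
  expect_error(estimate_latency(ref, mea2, max_shift_s = 1), "boundary|ambiguous")
  flat <- data.frame(t_s = tmea, y_vert_mm = rep(0, length(tmea)))
  expect_error(estimate_latency(ref, flat), "flat")
})

test_that("drift statistics summarise static stability", {
  t <- seq(0, 100, by = 0.5)
  const <- data.frame(t_s = t, z_long_mm = rep(5, length(t)))
  ds <- drift_stats(const, window_s = 20, axis = "z_long_mm")
  expect_equal(ds$overall_sd_mm, 0)
  expect_true(all(ds$windows$sd_mm == 0))
  # linear ramp 0 -> 1 mm: SD of a uniform grid is range/sqrt(12)
  ramp <- data.frame(t_s = t, z_long_mm = seq(0, 1, length.out = length(t)))
  expect_lt(abs(drift_stats(ramp, 20, "z_long_mm")$overall_sd_mm - 1 / sqrt(12)),
            0.005)
  set.seed(3)
  noisy <- data.frame(t_s = t, z_long_mm = rnorm(length(t), 0, 0.5))
  expect_lt(abs(drift_stats(noisy, 20, "z_long_mm")$overall_sd_mm - 0.5), 0.06)
  expect_error(drift_stats(const, window_s = 500), "shorter")
})

test_that("sinusoid fitting recovers programmed motion parameters", {
  set.seed(2)
  t <- seq(0, 20, by = 0.05)
  y <- 2 + 12 * sin(2 * pi * 0.25 * t + 0.7) + rnorm(length(t), 0, 0.1)
  fit <- fit_sinusoid(t, y, frequency_hz = 0.25)
  expect_lt(abs(fit$amplitude_mm - 12), 0.1)
  expect_lt(abs(fit$offset_mm - 2), 0.1)
  fit2 <- fit_sinusoid(t, y)
  expect_lt(abs(fit2$frequency_hz - 0.25), 0.005)
})

test_that("eval_report bundles the validation statistics", {
  set.seed(6)
  t <- seq(0, 60, by = 0.1)
  nominal <- 20 * sin(2 * pi * 0.2 * t)
  measured <- nominal + rnorm(length(t), 0.03, 0.13)
  rep <- eval_report(measured, nominal)
  expect_equal(unname(rep$tsr["1"]), 100)
  expect_lt(rep$mae_mm, 0.2)
  expect_gt(rep$pearson_r, 0.999)
  expect_equal(rep$n_pairs, length(t))
})
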