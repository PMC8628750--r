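test_that("linear_detrend removes lines exactly and is idempotent", {
  tc <- generate_timecourse(generator_config(flat_params(m = 0.5, b = 2),
                                             noise_sd = 0))
  out <- linear_detrend(tc)
  expect_lt(max(abs(out$values)), 1e-12)
  expect_equal(attr(out, "trend_slope"), 0.5, tolerance = 1e-10)

  # cosine + line: residual OLS slope ~ 0 (refit oracle)
  tc2 <- make_cosine_tc(A = 1, tau = 24, m = 0.3, b = 1)
  out2 <- linear_detrend(tc2)
  pts <- tc_points(out2)
  refit <- coef(lm(value ~ time, pts))
  expect_lt(abs(refit[["time"]]), 0.02)
  again <- linear_detrend(out2)
  expect_equal(again$values, out2$values, tolerance = 1e-10)

  expect_error(linear_detrend(timecourse(c(0, 4), cbind(c(1, 2)))), "3 distinct")
})

test_that("Lomb-Scargle periodogram peaks at the true period", {
  tc <- make_cosine_tc(A = 1, tau = 24)
  pg <- lomb_scargle_periodogram(tc)
  grid_step <- max(diff(sort(pg$period[abs(pg$period - 24) < 6])))
  expect_lt(abs(pg$period[which.max(pg$power)] - 24), grid_step + 1e-9)
  # power at the fundamental beats the half period
  p_at <- function(target) pg$power[which.min(abs(pg$period - target))]
  expect_gt(p_at(24), p_at(12))

  # constant series: zero powers, guarded
  const <- generate_timecourse(generator_config(flat_params(b = 3), noise_sd = 0))
  expect_true(all(lomb_scargle_periodogram(const)$power == 0))
})

test_that("LS permutation p-values respect the add-one floor", {
  tc <- make_cosine_tc(A = 1, tau = 24)
  r <- ls_permutation_test(tc, rhythm_test_config(n_permutations = 5000, seed = 1))
  expect_equal(r$p_value, 1 / 5001)
  expect_lt(abs(r$period_estimate - 24), 1.5)
  # determinism under a fixed seed
  r2 <- ls_permutation_test(tc, rhythm_test_config(n_permutations = 200, seed = 5))
  r3 <- ls_permutation_test(tc, rhythm_test_config(n_permutations = 200, seed = 5))
  expect_identical(r2$p_value, r3$p_value)
})

test_that("JTK template test matches templates and the tau oracle", {
  # data equal to a template: tau = 1 there
  times <- rep(seq(0, 48, 4), each = 2)
  tpl_vals <- cos(2 * pi * (times - 12) / 24)
  tc <- timecourse(seq(0, 48, 4),
                   matrix(tpl_vals, ncol = 2, byrow = TRUE))
  r <- jtk_cycle_test(tc, rhythm_test_config(n_permutations = 100, seed = 2))
  expect_equal(r$statistic, 1)
  expect_equal(r$period_estimate, 24)
  expect_equal(r$phase_estimate, 12)

  # negated data: the antiphase template wins with tau = 1
  tc_neg <- tc; tc_neg$values <- -tc_neg$values
  rn <- jtk_cycle_test(tc_neg, rhythm_test_config(n_permutations = 100, seed = 2))
  # equals 1 in exact arithmetic; floating-point ties in the cosine
  # template break a few tie pairs asymmetrically
  expect_gt(rn$statistic, 0.94)
  expect_equal(rn$period_estimate, 24)
  expect_equal(rn$phase_estimate, 0)

  # constant series: tau undefined -> p = 1 with flag
  const <- generate_timecourse(generator_config(flat_params(b = 1), noise_sd = 0))
  rc <- jtk_cycle_test(const, rhythm_test_config(n_permutations = 50, seed = 3))
  expect_equal(rc$p_value, 1)
  expect_true("constant_series" %in% rc$flags)
})

test_that("compiled Kendall tau equals the O(n^2) pair-count oracle", {
  set.seed(123)
  for (k in 1:100) {
    y <- rnorm(8)
    x <- cos(2 * pi * (seq(0, 28, 4) - sample(0:6, 1) * 4) / 24)
    if (k %% 3 == 0) y[sample(8, 2)] <- y[1]  # inject ties
    expect_identical(circapanel:::kendall_tau_b(x, y), oracle_kendall_tau_b(x, y))
  }
  # against R's own implementation on tie-free data
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(circapanel:::kendall_tau_b(x, y), cor(x, y, method = "kendall"),
               tolerance = 1e-12)
})

test_that("umbrella test finds sawtooth peaks and ignores monotone maps", {
  # sawtooth rising to mid-period then falling, one replicate, no
  # cross-group ties
  heights <- c(0, 1, 2, 3, 2.5, 1.5)
  times <- seq(0, 44, 4)
  vals <- heights[(times %% 24) / 4 + 1] + times * 1e-4
  tc <- timecourse(times, matrix(vals, ncol = 1))
  rc <- rhythm_test_config(n_permutations = 199, seed = 9)
  r <- umbrella_rain_test(tc, rc)
  expect_equal(r$phase_estimate, 12)
  expect_equal(r$p_value, 1 / 200)

  # rank invariance under a strictly monotone transform
  tc_exp <- tc; tc_exp$values <- exp(tc$values)
  r2 <- umbrella_rain_test(tc_exp, rc)
  expect_identical(r2$statistic, r$statistic)
  expect_identical(r2$p_value, r$p_value)

  const <- generate_timecourse(generator_config(flat_params(b = 2), noise_sd = 0))
  expect_equal(umbrella_rain_test(const, rc)$p_value, 1)
})

test_that("harmonic regression recovers amplitude and phase exactly", {
  A <- 0.7; theta <- 9.25; tau <- 24
  tc <- make_cosine_tc(A = A, theta = theta, tau = tau, b = 2)
  for (robust in c(FALSE, TRUE)) {
    f <- harmonic_regression_fit(tc, period = tau, robust = robust)
    expect_equal(f$amplitude, A, tolerance = 1e-9)
    expect_equal(f$phase, theta, tolerance = 1e-9)
    expect_equal(unname(f$coefficients["mesor"]), 2, tolerance = 1e-9)
  }
  const <- generate_timecourse(generator_config(flat_params(b = 4), noise_sd = 0))
  fc <- harmonic_regression_fit(const, 24)
  expect_equal(unname(fc$coefficients), c(4, 0, 0), tolerance = 1e-10)

  # pure noise: coefficients near zero, covariance scales with noise
  set.seed(4)
  covs <- replicate(40, {
    tcn <- make_noise_tc(seed = sample.int(1e6, 1), noise_sd = 0.3)
    f <- harmonic_regression_fit(tcn, 24)
    c(f$coefficients[2], f$vcov[2, 2])
  })
  expect_lt(abs(mean(covs[1, ])), 0.05)
  # empirical variance of beta_cos vs average model-based variance
  expect_equal(var(covs[1, ]), mean(covs[2, ]), tolerance = 0.5)
})

test_that("differential rhythmicity separates shifted rhythms", {
  rc <- rhythm_test_config(n_permutations = 199, seed = 12)
  a <- make_cosine_tc(A = 1, theta = 3, tau = 24, b = 2)
  same <- differential_rhythmicity_test(a, a, period = 24, config = rc,
                                        robust = FALSE)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  b <- make_cosine_tc(A = 1, theta = 3 + 12, tau = 24, b = 2)
  shift <- differential_rhythmicity_test(a, b, period = 24, config = rc)
  expect_lt(shift$p_value, 1e-6)

  # with noise, both analytic and permutation routes reject
  an <- make_cosine_tc(A = 1, theta = 3, tau = 24, b = 2, noise_sd = 0.1,
                       seed = 21)
  bn <- make_cosine_tc(A = 1, theta = 15, tau = 24, b = 2, noise_sd = 0.1,
                       seed = 22)
  expect_lt(differential_rhythmicity_test(an, bn, config = rc)$p_value, 1e-4)
  expect_equal(differential_rhythmicity_test(an, bn, config = rc,
                                             permute = TRUE)$p_value, 1 / 200)

  # mismatched grids are refused with the offending times named
  short <- timecourse(seq(0, 44, 4), a$values[1:12, ])
  expect_error(differential_rhythmicity_test(a, short, config = rc), "48")
})

test_that("detrending happens inside the differential test", {
  # same rhythm on very different linear trends: no differential signal
  rc <- rhythm_test_config(n_permutations = 99, seed = 30)
  a <- make_cosine_tc(A = 0.5, theta = 6, tau = 24, m = 0.00, b = 1,
                      noise_sd = 0.05, seed = 31)
  b <- make_cosine_tc(A = 0.5, theta = 6, tau = 24, m = 0.08, b = 1,
                      noise_sd = 0.05, seed = 32)
  r <- differential_rhythmicity_test(a, b, period = 24, config = rc)
  expect_gt(r$p_value, 0.01)
  # OLS slope on line + partial cosine cycles is mildly biased
  expect_lt(abs(unname(r$detrend$b["slope"]) - 0.08), 0.02)
})

test_that("period sweep helper returns one row per period", {
  a <- make_cosine_tc(A = 1, theta = 0, tau = 24, noise_sd = 0.1, seed = 41)
  b <- make_cosine_tc(A = 1, theta = 8, tau = 24, noise_sd = 0.1, seed = 42)
  sw <- differential_rhythmicity_sweep(a, b, periods = c(20, 24, 28),
                                       robust = FALSE)
  expect_equal(sw$period, c(20, 24, 28))
  expect_true(all(sw$p_value > 0 & sw$p_value <= 1))
})

test_that("label-permutation p-values are uniform on null pairs", {
  # non-robust fits here: the permutation scheme, not the M-estimator,
  # is the property under test, and 2000 sims must stay fast
  ps <- vapply(1:2000, function(i) {
    a <- make_noise_tc(seed = 60000 + 2 * i)
    b <- make_noise_tc(seed = 60001 + 2 * i)
    rc <- rhythm_test_config(n_permutations = 199, seed = i)
    differential_rhythmicity_test(a, b, period = 24, config = rc,
                                  robust = FALSE, permute = TRUE)$p_value
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif")$statistic)
  expect_lt(unname(ks), 0.05)
})
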