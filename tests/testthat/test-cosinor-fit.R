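test_that("noiseless fits recover the generating parameters", {
  for (p in table1_params()) {
    tc <- generate_timecourse(generator_config(p, noise_sd = 0))
    f <- fit_damped_cosine(tc)
    expect_true(f$converged)
    expect_lt(max_param_rel_err(f, p), 1e-3)
    expect_equal(f$r_squared, 1, tolerance = 1e-6)
    # objective no worse than at the generating truth (which is 0 here,
    # up to optimizer precision scaled to the data)
    expect_lt(f$objective, 1e-6 * sum(tc_points(tc)$value^2))
    expect_true(all(f$ci95[, 1] <= unlist(f$params)[c(1:6)] + 1e-9 |
                      is.na(f$ci95[, 1])))
  }
})

test_that("random truths within bounds are recovered (property sweep)", {
  # lambda and m are drawn away from zero: relative error is the metric
  # and is ill-conditioned at zero denominators (see methods vignette)
  set.seed(77)
  for (k in 1:50) {
    tau <- runif(1, 20, 44)
    p <- damped_cosine_params(A = runif(1, 0.1, 1),
                              lambda = sample(c(-1, 1), 1) * runif(1, 0.005, 0.045),
                              theta = runif(1, 0, tau), tau = tau,
                              m = sample(c(-1, 1), 1) * runif(1, 0.003, 0.04),
                              b = runif(1, 0.5, 2))
    tc <- generate_timecourse(generator_config(p, noise_sd = 0))
    f <- fit_damped_cosine(tc)
    expect_lt(max_param_rel_err(f, p), 1e-3)
  }
})

test_that("phase is canonical and start-invariant", {
  p <- damped_cosine_params(0.5, -0.01, 7.3, 26, 0.01, 1)
  tc <- generate_timecourse(generator_config(p, noise_sd = 0))
  f1 <- fit_damped_cosine(tc)
  expect_gte(f1$params$theta, 0)
  expect_lt(f1$params$theta, f1$params$tau)
  # different multistart phases/periods land on the same canonical optimum
  f2 <- fit_damped_cosine(tc, tau_starts = c(22, 30, 38),
                          lambda_starts = c(-0.02, 0.02))
  expect_equal(f1$params$theta, f2$params$theta, tolerance = 1e-5)
  expect_equal(f1$params$tau, f2$params$tau, tolerance = 1e-5)
})

test_that("degenerate and noisy inputs are handled sanely", {
  const <- generate_timecourse(generator_config(flat_params(b = 2), noise_sd = 0))
  f <- fit_damped_cosine(const)
  expect_true(f$converged)
  expect_lt(f$params$A, 1e-8)
  expect_lt(abs(f$params$m), 1e-10)
  expect_true("degenerate" %in% f$flags)

  # white noise on a flat truth: R^2 near zero, often negative; period
  # uncertainty large compared to a rhythmic fit
  set.seed(8)
  r2 <- replicate(20, {
    tc <- make_noise_tc(seed = sample.int(1e6, 1), noise_sd = 1)
    fit_damped_cosine(tc)$r_squared
  })
  # a 6-parameter fit to 78 noise points absorbs roughly 5/78 of the
  # variance, so R^2 concentrates just below ~0.1
  expect_lt(median(r2), 0.15)
  expect_gt(mean(r2 < 0.05), 0.2)

  expect_error(fit_damped_cosine(timecourse(c(0, 4, 8),
                                            cbind(c(1, 2, 1), c(2, 1, 2)))),
               "at least 7")
})

test_that("inverse-variance weighting caps zero-variance time points", {
  p <- table1_params()$H16N2_BMAL1
  tc <- generate_timecourse(generator_config(p, noise_sd = 0.1, seed = 31))
  tc$values[4, ] <- tc$values[4, 1]  # exact ties: zero variance at t = 12
  f <- fit_damped_cosine(tc)
  expect_true(f$converged)
  expect_true(all(is.finite(f$weights)))
  # capped weight equals the median-positive-variance weight
  v <- summarize_replicates(tc)$variance
  expect_equal(f$weights[4], 1 / median(v[v > 0]))
})

test_that("lambda and tau estimates respect their bounds", {
  # truth outside the damping bounds: estimate pinned at the boundary
  p <- damped_cosine_params(0.5, -0.09, 6, 26, 0, 1)
  tc <- generate_timecourse(generator_config(p, noise_sd = 0))
  f <- fit_damped_cosine(tc)
  expect_gte(f$params$lambda, -0.05)
  expect_lte(f$params$lambda, 0.05)
  expect_equal(f$params$lambda, -0.05, tolerance = 1e-6)
})

test_that("bounded-period fit test rejects in-range rhythms only", {
  tc <- make_cosine_tc(A = 1, lambda = 0.01, theta = 4, tau = 28, b = 2,
                       noise_sd = 0.05, seed = 51)
  r <- echo_style_rhythm_test(tc)
  expect_lt(r$p_value, 1e-6)
  expect_equal(r$period_estimate, 28, tolerance = 0.5)

  # out-of-range period of equal amplitude scores worse than in-range
  tc40 <- make_cosine_tc(A = 1, theta = 4, tau = 40, b = 2,
                         noise_sd = 0.2, seed = 52)
  tc28 <- make_cosine_tc(A = 1, theta = 4, tau = 28, b = 2,
                         noise_sd = 0.2, seed = 52)
  expect_gt(echo_style_rhythm_test(tc40)$p_value,
            echo_style_rhythm_test(tc28)$p_value)
  expect_true(echo_style_rhythm_test(tc40)$details$fit$params$tau <= 32 + 1e-6)
})

test_that("bounded-period fit test does not exceed its nominal level", {
  # the parametric F reference is conservative for this bounded
  # alternative (see the methods vignette); validity (type I <= nominal
  # + binomial noise) is the property asserted here, exact two-sided
  # calibration is probed in the acceptance suite
  nulls <- vapply(1:120, function(i)
    echo_style_rhythm_test(make_noise_tc(seed = 6000 + i))$p_value,
    numeric(1))
  expect_lt(mean(nulls < 0.05), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 120))
})

test_that("95% period CI covers the truth in most noisy replicates", {
  # Wald t-intervals: coverage a little under nominal is expected
  p <- table1_params()$H16N2_BMAL1
  hits <- vapply(1:500, function(s) {
    tc <- generate_timecourse(generator_config(p, noise_sd = 0.1,
                                               seed = 90000 + s))
    ci <- fit_damped_cosine(tc)$ci95["tau", ]
    ci[1] <= p$tau && p$tau <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.88)
})
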