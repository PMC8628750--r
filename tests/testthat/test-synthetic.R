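test_that("zero-noise generation equals the closed-form model everywhere", {
  for (p in table1_params()) {
    tc <- generate_timecourse(generator_config(p, noise_sd = 0))
    truth <- eval_damped_cosine(p, tc$times)
    for (j in seq_len(ncol(tc$values)))
      expect_equal(tc$values[, j], truth, tolerance = 1e-15)
  }
})

test_that("standard design yields 13 time points and the documented t0 value", {
  cfg <- generator_config(table1_params()$H16N2_BMAL1, noise_sd = 0)
  tc <- generate_timecourse(cfg)
  expect_length(tc$times, 13)
  expect_equal(tc$times, seq(0, 48, by = 4))
  # scalar oracle evaluated independently of the generator:
  # b + A * cos(-2*pi*theta/tau)
  v0 <- 0.910 + 0.432 * cos(-2 * pi * 11.402 / 26.546)
  expect_equal(unname(tc$values[1, 1]), v0, tolerance = 1e-12)
})

test_that("config invariants are enforced", {
  p <- flat_params()
  expect_error(generator_config(p, noise_sd = -1), "noise_sd")
  expect_error(generator_config(p, t_end = 0), "t_end")
  expect_error(generator_config(p, dt = 0), "dt")
  expect_error(generator_config(p, n_replicates = 0), "n_replicates")
  # a missing pattern emptying a whole time point is rejected
  bad <- cbind(rep(4, 6), 1:6)
  expect_error(generate_timecourse(generator_config(p, missing = bad)),
               "empty")
})

test_that("seed determinism and noise models behave", {
  p <- table1_params()$H16N2_PER2
  cfg <- generator_config(p, noise_sd = 0.1, seed = 99)
  expect_identical(generate_timecourse(cfg), generate_timecourse(cfg))
  cfg2 <- cfg; cfg2$seed <- 100
  expect_false(identical(generate_timecourse(cfg)$values,
                         generate_timecourse(cfg2)$values))
  # lognormal noise keeps values positive even for small baselines
  cfgl <- generator_config(flat_params(b = 0.05), noise_sd = 0.5,
                           noise_model = "lognormal", seed = 1)
  expect_true(all(generate_timecourse(cfgl)$values > 0))
})

test_that("per-time-point sample means converge to the model value", {
  p <- table1_params()$H16N2_BMAL1
  cfg <- generator_config(p, noise_sd = 0.3, n_replicates = 1e4, seed = 5)
  tc <- generate_timecourse(cfg)
  truth <- eval_damped_cosine(p, tc$times)
  expect_true(all(abs(rowMeans(tc$values) - truth) < 4 * 0.3 / 100))
})

test_that("generate_null has no periodic component", {
  cfg <- generator_config(flat_params(m = 0, b = 2.5), noise_sd = 0)
  tc <- generate_null(cfg)
  expect_true(all(tc$values == 2.5))
  cfg2 <- generator_config(table1_params()$H16N2_BMAL1, noise_sd = 0)
  tc2 <- generate_null(cfg2)  # params ignored except m and b
  expect_equal(tc2$values[, 1], 0.003 * tc2$times + 0.910, tolerance = 1e-12)
})

test_that("Ct tables invert the 2^-ddCt mapping", {
  # expression identically 1: target - reference Ct constant, value 1
  cfg <- generator_config(flat_params(b = 1), noise_sd = 0, gene = "BMAL1",
                          cell_line = "H16N2")
  ct <- generate_ct_table(cfg)
  tgt <- ct[ct$gene == "BMAL1", ]
  ref <- ct[ct$gene == "GAPDH", ]
  expect_equal(unique(tgt$ct - ref$ct), 5)
  tc <- relative_expression_ddct(ct, "BMAL1", "GAPDH")
  expect_true(all(abs(tc$values - 1) < 1e-12))

  # doubling expression at one time point lowers target Ct by 1 cycle
  base <- eval_damped_cosine(flat_params(b = 1), 0)
  expect_equal(log2(2 * base) - log2(base), 1)

  # zero-noise round trip recovers the truth (t0-calibrated) to 1e-9
  p <- table1_params()$H16N2_PER2
  cfg2 <- generator_config(p, noise_sd = 0, gene = "PER2", cell_line = "H16N2")
  ct2 <- generate_ct_table(cfg2)
  rec <- relative_expression_ddct(ct2, "PER2", "GAPDH", calibrator = "t0")
  truth <- eval_damped_cosine(p, rec$times)
  truth <- truth / truth[1]
  for (j in seq_len(ncol(rec$values)))
    expect_true(all(abs(rec$values[, j] / truth - 1) < 1e-9))

  expect_error(generate_ct_table(
    generator_config(flat_params(b = -1), noise_sd = 0)), "positive")
})

test_that("panel presets reproduce the stated design", {
  panel <- generate_panel("H16N2", noise_sd = 0, seed = 1)
  expect_named(panel, c("H16N2:BMAL1", "H16N2:PER2"))
  # peak-time oracle on the truth parameters: offset about 10.9 h
  pk_b <- peak_times(table1_params()$H16N2_BMAL1)[1]
  pk_p <- peak_times(table1_params()$H16N2_PER2)[1]
  expect_equal(round(abs(pk_b - pk_p), 1), 10.9)

  mt <- generate_panel("21MT-1", noise_sd = 0.05, seed = 2)
  n_per_tp <- rowSums(!is.na(mt[["21MT-1:BMAL1"]]$values))
  expect_equal(sum(n_per_tp == 5), 4)
  expect_equal(sum(n_per_tp == 6), 9)

  expect_identical(generate_panel(seed = 7), generate_panel(seed = 7))
  expect_error(generate_panel("MCF7"), "unknown preset")

  full <- generate_panel(seed = 3)
  expect_length(full, 6)
})
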