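# Independent oracles and shared fixtures. Oracles are deliberately
# naive (brute force / closed form) and never call the code paths they
# check.

# O(n^2) tie-corrected Kendall tau-b by explicit pair counting
oracle_kendall_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]
      dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (sign(dx) == sign(dy)) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

oracle_median <- function(x) {
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

oracle_variance <- function(x) {
  x <- x[!is.na(x)]
  sum((x - sum(x) / length(x))^2) / (length(x) - 1)
}

# printed circadian parameter columns for the built-in panel presets
table1_params <- function() {
  list(
    H16N2_BMAL1 = damped_cosine_params(0.432, -0.015, 11.402, 26.546, 0.003, 0.910),
    H16N2_PER2 = damped_cosine_params(0.309, -0.011, 26.952, 26.470, 0.018, 0.485),
    `21PT_BMAL1` = damped_cosine_params(0.085, -0.050, 6.001, 35.745, 0.023, 0.344),
    `21PT_PER2` = damped_cosine_params(0.173, -0.028, 31.473, 30.621, 0.032, 0.254),
    `21MT1_PER2` = damped_cosine_params(0.208, -0.026, 27.033, 27.206, 0.006, 0.876))
}

# quick constructor for a cosine time course on the standard design
make_cosine_tc <- function(A = 1, lambda = 0, theta = 0, tau = 24, m = 0,
                           b = 0, noise_sd = 0, seed = NULL,
                           n_replicates = 6, t_end = 48, dt = 4) {
  generate_timecourse(generator_config(
    damped_cosine_params(A, lambda, theta, tau, m, b),
    t_end = t_end, dt = dt, n_replicates = n_replicates,
    noise_sd = noise_sd, seed = seed))
}

flat_params <- function(m = 0, b = 1) damped_cosine_params(0, 0, 0, 24, m = m, b = b)

# white-noise series on the standard design
make_noise_tc <- function(seed, noise_sd = 0.2, b = 1, m = 0)
  generate_timecourse(generator_config(flat_params(m = m, b = b),
                                       noise_sd = noise_sd, seed = seed))

# canonical relative parameter error between a fit and a truth, with the
# phase compared modulo the period
max_param_rel_err <- function(fit, truth) {
  est <- c(fit$params$A, fit$params$lambda, fit$params$theta %% fit$params$tau,
           fit$params$tau, fit$params$m, fit$params$b)
  tr <- c(truth$A, truth$lambda, truth$theta %% truth$tau,
          truth$tau, truth$m, truth$b)
  max(abs(est - tr) / pmax(abs(tr), 1e-12))
}

binom99 <- function(alpha, n) {
  # exact binomial central 99% interval for a proportion
  lo <- qbinom(0.005, n, alpha) / n
  hi <- qbinom(0.995, n, alpha) / n
  c(lo, hi)
}
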