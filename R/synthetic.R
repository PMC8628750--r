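#' Generator configuration for synthetic time courses
#'
#' Encodes the standard serum-shock qPCR design: sampling every `dt = 4` h
#' from 0 to 48 h (13 time points) with 6 exchangeable replicates
#' (3 biological replicates in each of 2 experiments), additive Gaussian
#' noise by default, and an optional missingness pattern.
#'
#' @param params a [damped_cosine_params()] object: the generative truth.
#' @param t_start,t_end,dt sampling design in hours (defaults 0, 48, 4).
#' @param n_replicates replicates per time point (default 6).
#' @param noise_sd standard deviation of per-observation noise in
#'   relative-expression units (Gaussian) or log-scale sd (lognormal).
#' @param noise_model `"gaussian"` (additive) or `"lognormal"`
#'   (multiplicative, keeps values positive).
#' @param missing two-column matrix or data.frame of (time index,
#'   replicate index) pairs (1-based) to drop.
#' @param seed integer seed; identical configs with identical seeds give
#'   identical output.
#' @param cell_line,gene labels stamped on generated series.
#'
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(params,
                             t_start = 0, t_end = 48, dt = 4,
                             n_replicates = 6,
                             noise_sd = 0,
                             noise_model = c("gaussian", "lognormal"),
                             missing = NULL,
                             seed = NULL,
                             cell_line = "synthetic", gene = "gene") {
  params <- as_damped_cosine_params(params)
  noise_model <- match.arg(noise_model)
  if (t_end <= t_start) stop("t_end must be > t_start")
  if (dt <= 0) stop("dt must be > 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(missing)) {
    missing <- as.matrix(missing)
    if (ncol(missing) != 2) stop("'missing' needs two columns: time index, replicate index")
    storage.mode(missing) <- "integer"
  }
  structure(list(params = params, t_start = t_start, t_end = t_end, dt = dt,
                 n_replicates = n_replicates, noise_sd = noise_sd,
                 noise_model = noise_model, missing = missing, seed = seed,
                 cell_line = cell_line, gene = gene),
            class = "generator_config")
}

config_times <- function(config) {
  n_pts <- floor((config$t_end - config$t_start) / config$dt) + 1
  config$t_start + config$dt * (seq_len(n_pts) - 1)
}

apply_missing <- function(values, missing, times) {
  if (is.null(missing)) return(values)
  if (any(missing[, 1] < 1 | missing[, 1] > nrow(values)) ||
      any(missing[, 2] < 1 | missing[, 2] > ncol(values)))
    stop("missing pattern indexes outside the design")
  values[missing] <- NA_real_
  n_present <- rowSums(!is.na(values))
  if (any(n_present < 1))
    stop("missing pattern would empty time point(s) at t = ",
         paste(times[n_present < 1], collapse = ", "))
  values
}

add_noise <- function(truth, config) {
  n <- length(truth)
  switch(config$noise_model,
         gaussian = truth + stats::rnorm(n, 0, config$noise_sd),
         lognormal = truth * exp(stats::rnorm(n, 0, config$noise_sd)))
}

#' Generate a rhythmic synthetic time course
#'
#' Evaluates the damped cosine truth at the design points and adds
#' per-observation noise; with `noise_sd = 0` every value equals the
#' closed-form model evaluation exactly.
#'
#' @param config a [generator_config()].
#' @return A [timecourse] object.
#' @export
generate_timecourse <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  times <- config_times(config)
  truth <- eval_damped_cosine(config$params, times)
  values <- with_seed(config$seed, {
    matrix(add_noise(rep(truth, config$n_replicates), config),
           nrow = length(times), ncol = config$n_replicates)
  })
  values <- apply_missing(values, config$missing, times)
  timecourse(times, values, cell_line = config$cell_line, gene = config$gene,
             experiment = default_experiment_labels(config$n_replicates))
}

#' Generate an arrhythmic (null) time course
#'
#' Linear baseline `b + m t` plus i.i.d. noise, no periodic component.
#' Amplitude/damping/phase/period in `config$params` are ignored. Used to
#' study type-I error of the rhythmicity battery.
#'
#' @inheritParams generate_timecourse
#' @return A [timecourse] object.
#' @export
generate_null <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  flat <- config
  flat$params <- damped_cosine_params(A = 0, lambda = 0, theta = 0, tau = 24,
                                      m = config$params$m, b = config$params$b)
  generate_timecourse(flat)
}

default_experiment_labels <- function(n_replicates) {
  # 3 biological replicates x 2 experiments when n = 6; otherwise a
  # single-batch label. Bookkeeping only: no batch effect is generated.
  if (n_replicates == 6) rep(c("exp1", "exp2"), each = 3)
  else rep("exp1", n_replicates)
}

#' Generate a matched qPCR Ct table from an expression truth
#'
#' Inverse of the 2^-ddCt mapping: the reference gene is held at
#' `reference_level` cycles (plus optional jitter) and the target-gene Ct
#' is `reference_level + calibrator_offset - log_base(expression)`, so
#' lower Ct means more template. Round-tripping through
#' [relative_expression_ddct()] recovers the expression series up to the
#' calibrator normalization.
#'
#' @inheritParams generate_timecourse
#' @param reference_level reference-gene Ct level (cycles, default 20).
#' @param efficiency_base amplification base (default 2, i.e. perfect
#'   doubling per cycle).
#' @param calibrator_offset constant added to target Ct (cycles, default 5).
#' @param reference_gene,target_gene gene names written into the table.
#' @param ct_jitter_sd optional Gaussian jitter (cycles) applied to the
#'   reference-gene Ct values.
#' @return A long-format data.frame of class `ct_table` with columns
#'   `cell_line, gene, time_h, replicate, experiment, ct`.
#' @export
generate_ct_table <- function(config, reference_level = 20,
                              efficiency_base = 2,
                              calibrator_offset = 5,
                              reference_gene = "GAPDH",
                              target_gene = NULL,
                              ct_jitter_sd = 0) {
  stopifnot(inherits(config, "generator_config"))
  if (efficiency_base <= 1) stop("efficiency_base must be > 1")
  tc <- generate_timecourse(config)
  expr <- tc$values
  if (any(expr[!is.na(expr)] <= 0))
    stop("expression truth must be strictly positive to map to Ct; ",
         "use lognormal noise or a higher baseline")
  if (is.null(target_gene)) target_gene <- config$gene
  idx <- which(!is.na(expr), arr.ind = TRUE)
  times <- tc$times[idx[, 1]]
  reps <- idx[, 2]
  exper <- default_experiment_labels(config$n_replicates)[reps]
  ref_ct <- rep(reference_level, nrow(idx))
  if (ct_jitter_sd > 0) {
    jitter_seed <- if (is.null(config$seed)) NULL else config$seed + 1L
    ref_ct <- with_seed(jitter_seed,
                        ref_ct + stats::rnorm(nrow(idx), 0, ct_jitter_sd))
  }
  target_ct <- ref_ct + calibrator_offset - log(expr[idx], base = efficiency_base)
  out <- rbind(
    data.frame(cell_line = config$cell_line, gene = target_gene,
               time_h = times, replicate = reps, experiment = exper,
               ct = target_ct, stringsAsFactors = FALSE),
    data.frame(cell_line = config$cell_line, gene = reference_gene,
               time_h = times, replicate = reps, experiment = exper,
               ct = ref_ct, stringsAsFactors = FALSE))
  out <- out[order(out$gene, out$time_h, out$replicate), ]
  rownames(out) <- NULL
  class(out) <- c("ct_table", "data.frame")
  out
}

# Circadian parameter presets for the three-cell-line panel: normal
# breast epithelium (H16N2), atypical ductal hyperplasia (21PT) and
# invasive metastatic carcinoma (21MT-1), genes BMAL1 and PER2. The
# 21MT-1 BMAL1 series has no printed sinusoidal parameters (the fit
# failed on the real data), so its preset is the null generator with the
# 21MT-1 PER2 linear trend.
panel_truths <- function() {
  list(
    "H16N2" = list(
      BMAL1 = damped_cosine_params(A = 0.432, lambda = -0.015, theta = 11.402,
                                   tau = 26.546, m = 0.003, b = 0.910),
      PER2 = damped_cosine_params(A = 0.309, lambda = -0.011, theta = 26.952,
                                  tau = 26.470, m = 0.018, b = 0.485)),
    "21PT" = list(
      BMAL1 = damped_cosine_params(A = 0.085, lambda = -0.050, theta = 6.001,
                                   tau = 35.745, m = 0.023, b = 0.344),
      PER2 = damped_cosine_params(A = 0.173, lambda = -0.028, theta = 31.473,
                                  tau = 30.621, m = 0.032, b = 0.254)),
    "21MT-1" = list(
      BMAL1 = NULL, # arrhythmic: null model on the PER2 linear trend
      PER2 = damped_cosine_params(A = 0.208, lambda = -0.026, theta = 27.033,
                                  tau = 27.206, m = 0.006, b = 0.876))
  )
}

#' Names of the built-in panel presets
#' @return Character vector of cell-line preset names.
#' @export
panel_presets <- function() names(panel_truths())

# Fixed n = 5 pattern for the metastatic line: 4 of 13 time points lose
# one replicate (the last replicate at t = 8, 20, 32, 44 h).
mt1_missing_pattern <- function(n_replicates) {
  cbind(time = c(3L, 6L, 9L, 12L), replicate = rep(n_replicates, 4L))
}

#' Generate a synthetic cell-line panel
#'
#' Builds `timecourse` objects for the requested cell-line presets, two
#' genes (BMAL1 and PER2) per cell line, with the standard design
#' (0-48 h every 4 h, 6 replicates). The `"21MT-1"` preset reproduces the
#' n = 5 missingness at 4 time points and uses an arrhythmic (null)
#' BMAL1 series.
#'
#' @param preset character vector of preset names (see [panel_presets()]);
#'   default all three, giving six time courses.
#' @param noise_sd per-observation noise sd (default 0.05
#'   relative-expression units; see the methods vignette).
#' @param noise_model `"gaussian"` or `"lognormal"`.
#' @param seed integer seed for the whole panel (each series draws a
#'   distinct sub-seed).
#' @param n_replicates replicates per time point (default 6).
#' @return Named list of [timecourse] objects, names `"<cell line>:<gene>"`.
#' @export
generate_panel <- function(preset = panel_presets(), noise_sd = 0.05,
                           noise_model = "gaussian", seed = NULL,
                           n_replicates = 6) {
  truths <- panel_truths()
  unknown <- setdiff(preset, names(truths))
  if (length(unknown))
    stop("unknown preset(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(names(truths), collapse = ", "))
  out <- list()
  k <- 0L
  for (cl in preset) {
    for (gene in c("BMAL1", "PER2")) {
      k <- k + 1L
      sub_seed <- if (is.null(seed)) NULL else (seed + 1000L * k) %% .Machine$integer.max
      p <- truths[[cl]][[gene]]
      missing <- if (cl == "21MT-1") mt1_missing_pattern(n_replicates) else NULL
      if (is.null(p)) {
        trend <- truths[[cl]]$PER2
        cfg <- generator_config(
          params = damped_cosine_params(0, 0, 0, 24, m = trend$m, b = trend$b),
          noise_sd = noise_sd, noise_model = noise_model, missing = missing,
          seed = sub_seed, cell_line = cl, gene = gene,
          n_replicates = n_replicates)
        out[[paste(cl, gene, sep = ":")]] <- generate_null(cfg)
      } else {
        cfg <- generator_config(
          params = p, noise_sd = noise_sd, noise_model = noise_model,
          missing = missing, seed = sub_seed, cell_line = cl, gene = gene,
          n_replicates = n_replicates)
        out[[paste(cl, gene, sep = ":")]] <- generate_timecourse(cfg)
      }
    }
  }
  out
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}
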