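#' Read a long-format time-course CSV
#'
#' Expects columns `cell_line, gene, time_h, replicate, experiment` and
#' exactly one of `ct` (raw cycle thresholds) or `value` (relative
#' expression). Times are literal hours. Duplicate
#' `(cell_line, gene, time_h, replicate, experiment)` keys are an error.
#'
#' @param path CSV file path.
#' @return A `ct_table` data.frame when the file has a `ct` column; a
#'   named list of [timecourse] objects (one per cell line x gene) when
#'   it has a `value` column.
#' @export
read_timecourse_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("cell_line", "gene", "time_h", "replicate")
  miss <- setdiff(required, names(d))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (!"experiment" %in% names(d)) d$experiment <- "exp1"
  has_ct <- "ct" %in% names(d)
  has_value <- "value" %in% names(d)
  if (has_ct == has_value)
    stop("file must have exactly one of 'ct' or 'value'")
  vcol <- if (has_ct) "ct" else "value"
  if (!is.numeric(d$time_h)) stop("'time_h' must be numeric")
  if (!is.numeric(d[[vcol]])) stop("'", vcol, "' must be numeric")
  key <- paste(d$cell_line, d$gene, d$time_h, d$replicate, d$experiment, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate key row(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (has_ct) {
    class(d) <- c("ct_table", "data.frame")
    return(d)
  }
  split_keys <- unique(d[c("cell_line", "gene")])
  out <- list()
  for (i in seq_len(nrow(split_keys))) {
    sub <- d[d$cell_line == split_keys$cell_line[i] &
               d$gene == split_keys$gene[i], , drop = FALSE]
    rep_id <- paste(sub$replicate, sub$experiment, sep = ".")
    times <- sort(unique(sub$time_h))
    reps <- sort(unique(rep_id))
    values <- matrix(NA_real_, length(times), length(reps),
                     dimnames = list(NULL, reps))
    values[cbind(match(sub$time_h, times), match(rep_id, reps))] <- sub$value
    out[[paste(split_keys$cell_line[i], split_keys$gene[i], sep = ":")]] <-
      timecourse(times, values, cell_line = split_keys$cell_line[i],
                 gene = split_keys$gene[i])
  }
  out
}

#' Write time courses to the long-format CSV
#'
#' @param tcs a [timecourse] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(tcs, path) {
  if (inherits(tcs, "timecourse")) tcs <- list(tcs)
  rows <- lapply(tcs, function(tc) {
    pts <- tc_points(tc)
    exper <- if (!is.null(tc$experiment)) {
      tc$experiment[match(pts$replicate, colnames(tc$values))]
    } else "exp1"
    data.frame(cell_line = tc$cell_line, gene = tc$gene, time_h = pts$time,
               replicate = pts$replicate, experiment = exper,
               value = pts$value, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param input path to a long-format CSV (Ct or expression), or `NULL`
#'   to simulate from `preset`.
#' @param preset cell-line preset names for simulation (see
#'   [panel_presets()]).
#' @param noise_sd simulation noise sd.
#' @param genes target genes.
#' @param reference_gene reference gene for ddCt quantification.
#' @param calibrator ddCt calibrator rule, `"t0"` or `"mean"`.
#' @param tests battery members to run, a subset of
#'   `c("rain", "lomb_scargle", "jtk", "echo")`.
#' @param rhythm a [rhythm_test_config()].
#' @param lambda_bounds,tau_bounds fit bounds (see [fit_damped_cosine()]).
#' @param echo_period_range period window (h) for the bounded-period fit
#'   test.
#' @param pairs 2-column matrix of cell-line pairs for the differential
#'   test; `NULL` means all pairs.
#' @param diff_period shared period (h) for the differential test.
#' @param alpha significance level used for the summary count column.
#' @param normalize apply per-replicate mean normalization before
#'   analysis.
#' @param out_dir output directory for TSV/CSV results, or `NULL`.
#' @param seed master seed; all stage seeds derive from it.
#' @param verbose print per-stage progress.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(input = NULL, preset = panel_presets(),
                            noise_sd = 0.05,
                            genes = c("BMAL1", "PER2"),
                            reference_gene = "GAPDH",
                            calibrator = "t0",
                            tests = c("rain", "lomb_scargle", "jtk", "echo"),
                            rhythm = rhythm_test_config(),
                            lambda_bounds = c(-0.05, 0.05),
                            tau_bounds = c(18, 48),
                            echo_period_range = c(24, 32),
                            pairs = NULL, diff_period = 24,
                            alpha = 0.001, normalize = TRUE,
                            out_dir = NULL, seed = 1L, verbose = FALSE) {
  tests <- match.arg(tests, several.ok = TRUE)
  structure(list(input = input, preset = preset, noise_sd = noise_sd,
                 genes = genes, reference_gene = reference_gene,
                 calibrator = calibrator, tests = tests, rhythm = rhythm,
                 lambda_bounds = lambda_bounds, tau_bounds = tau_bounds,
                 echo_period_range = echo_period_range, pairs = pairs,
                 diff_period = diff_period, alpha = alpha,
                 normalize = normalize, out_dir = out_dir,
                 seed = as.integer(seed), verbose = verbose),
            class = "analysis_config")
}

derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7907 * k) %% 2147483563) + 1L
}

#' Run the rhythmicity battery on one series
#'
#' @param tc a [timecourse].
#' @param config an [analysis_config()] (battery selection, rhythm
#'   settings, fit bounds).
#' @return data.frame: one row per test with method, statistic, p_value,
#'   period/phase estimates and error messages for failed stages.
#' @export
run_rhythm_battery <- function(tc, config = analysis_config()) {
  rows <- lapply(config$tests, function(test) {
    rc <- config$rhythm
    rc$seed <- derive_seed(config$seed, match(test, config$tests) +
                             100L * utf8_sum(tc_label(tc)))
    r <- tryCatch(switch(test,
        rain = umbrella_rain_test(tc, rc),
        lomb_scargle = ls_permutation_test(tc, rc),
        jtk = jtk_cycle_test(tc, rc),
        echo = echo_style_rhythm_test(tc, config$echo_period_range[1],
                                      config$echo_period_range[2],
                                      config$lambda_bounds)),
      error = function(e) e)
    if (inherits(r, "error")) {
      data.frame(cell_line = tc$cell_line, gene = tc$gene, method = test,
                 statistic = NA_real_, p_value = NA_real_,
                 period_estimate = NA_real_, phase_estimate = NA_real_,
                 n_permutations = rc$n_permutations,
                 seed = if (is.null(rc$seed)) NA_integer_ else rc$seed,
                 error = conditionMessage(r), stringsAsFactors = FALSE)
    } else {
      data.frame(cell_line = tc$cell_line, gene = tc$gene, method = r$method,
                 statistic = r$statistic, p_value = r$p_value,
                 period_estimate = r$period_estimate,
                 phase_estimate = r$phase_estimate,
                 n_permutations = rc$n_permutations,
                 seed = if (is.null(rc$seed)) NA_integer_ else rc$seed,
                 error = "", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

utf8_sum <- function(s) sum(utf8ToInt(s)) %% 1000L

#' Build a circadian parameter table from fits
#'
#' One row per (cell line, gene) with Baseline, Amplitude, DampingRate,
#' Phase, Slope and Period estimates, each with its standard error and
#' 95% CI, plus R^2 and a converged flag. Rows whose fit failed to
#' converge, or whose fit explains no variance (R^2 < 0, a lack of fit),
#' have their estimates masked to `NA` and `reported = FALSE`.
#'
#' @param fits named list of `cosinor_fit` objects, names
#'   `"<cell line>:<gene>"`.
#' @return data.frame of class `parameter_table`.
#' @export
parameter_table <- function(fits) {
  par_map <- c(Baseline = "b", Amplitude = "A", DampingRate = "lambda",
               Phase = "theta", Slope = "m", Period = "tau")
  idx_map <- c(b = 6, A = 1, lambda = 2, theta = 3, tau = 4, m = 5)
  rows <- lapply(names(fits), function(nm) {
    fit <- fits[[nm]]
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    row <- data.frame(cell_line = parts[1], gene = parts[2],
                      stringsAsFactors = FALSE)
    ok <- isTRUE(fit$converged)
    reported <- ok && !is.na(fit$r_squared) && fit$r_squared >= 0 &&
      !"degenerate" %in% fit$flags
    for (col in names(par_map)) {
      i <- idx_map[[par_map[[col]]]]
      if (reported) {
        est <- switch(par_map[[col]], b = fit$params$b, A = fit$params$A,
                      lambda = fit$params$lambda, theta = fit$params$theta,
                      tau = fit$params$tau, m = fit$params$m)
        row[[col]] <- est
        row[[paste0(col, "_se")]] <- unname(fit$std_errors[i])
        row[[paste0(col, "_ci_low")]] <- fit$ci95[i, 1]
        row[[paste0(col, "_ci_high")]] <- fit$ci95[i, 2]
      } else {
        row[[col]] <- NA_real_
        row[[paste0(col, "_se")]] <- NA_real_
        row[[paste0(col, "_ci_low")]] <- NA_real_
        row[[paste0(col, "_ci_high")]] <- NA_real_
      }
    }
    row$R2 <- if (ok) fit$r_squared else NA_real_
    row$Converged <- ok
    row$Reported <- reported
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("parameter_table", "data.frame")
  out
}

#' Run the full analysis pipeline
#'
#' Simulate (or ingest) -> quantify -> normalize -> rhythmicity battery
#' -> pairwise differential rhythmicity -> parameter table. Per-series
#' failures are logged and do not abort the run. Identical config and
#' seed give identical outputs.
#'
#' @param config an [analysis_config()].
#' @return A list of class `analysis_result`: `parameter_table`,
#'   `rhythm_results`, `differential_results`, `phase_relationships`
#'   (peak-time offset and anti-phase flag between the two genes within
#'   each cell line), `fits`, `timecourses`, `manifest`, `errors`. When `config$out_dir` is set,
#'   `parameter_table.csv`, `rhythm_results.tsv`,
#'   `differential_results.tsv` and `manifest.json` are written there.
#' @export
run_analysis <- function(config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  errors <- list()
  note <- function(stage, e) {
    errors[[length(errors) + 1L]] <<- list(stage = stage,
                                           message = conditionMessage(e))
    if (config$verbose) message("[error] ", stage, ": ", conditionMessage(e))
  }

  # --- ingest or simulate -------------------------------------------------
  if (!is.null(config$input)) {
    raw <- read_timecourse_csv(config$input)
    if (inherits(raw, "ct_table")) {
      tcs <- list()
      for (cl in unique(raw$cell_line)) {
        sub <- raw[raw$cell_line == cl, , drop = FALSE]
        for (g in intersect(config$genes, unique(sub$gene))) {
          key <- paste(cl, g, sep = ":")
          tc <- tryCatch(relative_expression_ddct(sub, target = g,
                                                  reference = config$reference_gene,
                                                  calibrator = config$calibrator),
                         error = function(e) e)
          if (inherits(tc, "error")) note(paste("quantify", key), tc)
          else tcs[[key]] <- tc
        }
      }
    } else tcs <- raw
  } else {
    tcs <- generate_panel(config$preset, noise_sd = config$noise_sd,
                          seed = config$seed)
  }

  if (config$normalize) {
    for (nm in names(tcs)) {
      r <- tryCatch(mean_normalize(tcs[[nm]]), error = function(e) e)
      if (inherits(r, "error")) note(paste("normalize", nm), r)
      else tcs[[nm]] <- r
    }
  }

  # --- rhythmicity battery + fits ----------------------------------------
  rhythm_rows <- list()
  fits <- list()
  for (nm in names(tcs)) {
    if (config$verbose) message("[series] ", nm)
    rhythm_rows[[nm]] <- run_rhythm_battery(tcs[[nm]], config)
    fit <- tryCatch(fit_damped_cosine(tcs[[nm]],
                                      lambda_bounds = config$lambda_bounds,
                                      tau_bounds = config$tau_bounds),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      note(paste("fit", nm), fit)
      fits[[nm]] <- structure(list(converged = FALSE, r_squared = NA_real_,
                                   flags = "error"), class = "cosinor_fit")
    } else fits[[nm]] <- fit
  }
  rhythm_results <- do.call(rbind, rhythm_rows)
  rownames(rhythm_results) <- NULL
  rhythm_results$significant <- !is.na(rhythm_results$p_value) &
    rhythm_results$p_value < config$alpha

  # --- pairwise differential rhythmicity ---------------------------------
  cell_lines <- unique(vapply(tcs, function(tc) tc$cell_line, character(1)))
  pairs <- config$pairs
  if (is.null(pairs) && length(cell_lines) >= 2)
    pairs <- t(utils::combn(cell_lines, 2))
  diff_rows <- list()
  if (!is.null(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      for (g in config$genes) {
        ka <- paste(pairs[i, 1], g, sep = ":")
        kb <- paste(pairs[i, 2], g, sep = ":")
        if (!ka %in% names(tcs) || !kb %in% names(tcs)) next
        rc <- config$rhythm
        rc$seed <- derive_seed(config$seed, 500L + 7L * i + utf8_sum(g))
        r <- tryCatch(differential_rhythmicity_test(tcs[[ka]], tcs[[kb]],
                                                    period = config$diff_period,
                                                    config = rc),
                      error = function(e) e)
        if (inherits(r, "error")) {
          note(paste("differential", ka, "vs", kb), r)
          diff_rows[[paste(ka, kb)]] <- data.frame(
            cell_line_a = pairs[i, 1], cell_line_b = pairs[i, 2], gene = g,
            period = config$diff_period, statistic = NA_real_,
            p_value = NA_real_, error = conditionMessage(r),
            stringsAsFactors = FALSE)
        } else {
          diff_rows[[paste(ka, kb)]] <- data.frame(
            cell_line_a = pairs[i, 1], cell_line_b = pairs[i, 2], gene = g,
            period = r$period, statistic = r$statistic, p_value = r$p_value,
            error = "", stringsAsFactors = FALSE)
        }
      }
    }
  }
  differential_results <- if (length(diff_rows)) do.call(rbind, diff_rows)
                          else data.frame()
  rownames(differential_results) <- NULL

  # --- phase relationship between the two genes within each cell line ---
  phase_rows <- list()
  for (cl in cell_lines) {
    keys <- paste(cl, config$genes, sep = ":")
    if (length(keys) != 2 || !all(keys %in% names(fits))) next
    fa <- fits[[keys[1]]]; fb <- fits[[keys[2]]]
    if (!isTRUE(fa$converged) || !isTRUE(fb$converged)) next
    pr <- phase_relationship(fa, fb)
    phase_rows[[cl]] <- data.frame(cell_line = cl,
                                   gene_a = config$genes[1],
                                   gene_b = config$genes[2],
                                   offset_h = pr$offset,
                                   mean_period = pr$mean_period,
                                   antiphase = pr$antiphase,
                                   stringsAsFactors = FALSE)
  }
  phase_relationships <- if (length(phase_rows)) do.call(rbind, phase_rows)
                         else data.frame()
  rownames(phase_relationships) <- NULL

  ptab <- parameter_table(fits)
  # per-series count of battery members significant at alpha
  sig_count <- stats::aggregate(significant ~ cell_line + gene,
                                data = rhythm_results, FUN = sum)
  names(sig_count)[3] <- "n_tests_significant"
  ptab <- merge(ptab, sig_count, by = c("cell_line", "gene"),
                all.x = TRUE, sort = FALSE)
  class(ptab) <- c("parameter_table", "data.frame")

  manifest <- list(package = "circapanel",
                   version = as.character(utils::packageVersion("circapanel")),
                   seed = config$seed,
                   config_hash = config_hash(config),
                   n_series = length(tcs),
                   tests = config$tests,
                   n_errors = length(errors))

  out <- structure(list(parameter_table = ptab,
                        rhythm_results = rhythm_results,
                        differential_results = differential_results,
                        phase_relationships = phase_relationships,
                        fits = fits, timecourses = tcs,
                        manifest = manifest, errors = errors),
                   class = "analysis_result")
  if (!is.null(config$out_dir)) write_analysis_result(out, config$out_dir)
  out
}

config_hash <- function(config) {
  # hash of the scientific configuration: output location and verbosity
  # do not change results
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  cfg$verbose <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg), tmp)
  unname(tools::md5sum(tmp))
}

write_analysis_result <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$parameter_table,
                   file.path(out_dir, "parameter_table.csv"), row.names = FALSE)
  utils::write.table(result$rhythm_results,
                     file.path(out_dir, "rhythm_results.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(result$differential_results,
                     file.path(out_dir, "differential_results.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.analysis_result <- function(x, ...) {
  cat("<analysis_result>\n")
  cat("  series:", length(x$timecourses), "\n")
  cat("  rhythm tests:", nrow(x$rhythm_results), "rows\n")
  cat("  differential tests:", nrow(x$differential_results), "rows\n")
  cat("  errors:", length(x$errors), "\n")
  invisible(x)
}
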