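#' Relative expression via the 2^-ddCt method
#'
#' For each (time, replicate) pair: `dCt = Ct_target - Ct_reference`,
#' `ddCt = dCt - dCt_calibrator`, and the relative expression is
#' `2^(-ddCt)`. The calibrator is replicate-matched: either that
#' replicate's dCt at the first time point (`"t0"`, the sample taken
#' immediately after synchronization; the conventional choice) or the
#' replicate's mean dCt over time (`"mean"`).
#'
#' Adding a constant to all Ct values of both genes leaves the output
#' unchanged, and all outputs are strictly positive.
#'
#' @param ct a `ct_table` data.frame (columns `cell_line, gene, time_h,
#'   replicate, experiment, ct`), e.g. from [generate_ct_table()] or
#'   [read_timecourse_csv()].
#' @param target target gene name (default `"BMAL1"`).
#' @param reference reference gene name (default `"GAPDH"`).
#' @param calibrator `"t0"` or `"mean"`.
#' @return A [timecourse] of relative expression for the single cell line
#'   in `ct`, or a named list of them when several cell lines are present.
#' @export
relative_expression_ddct <- function(ct, target = "BMAL1",
                                     reference = "GAPDH",
                                     calibrator = c("t0", "mean")) {
  calibrator <- match.arg(calibrator)
  ct <- as.data.frame(ct)
  required <- c("cell_line", "gene", "time_h", "replicate", "ct")
  miss <- setdiff(required, names(ct))
  if (length(miss)) stop("ct table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"experiment" %in% names(ct)) ct$experiment <- "exp1"
  cls <- unique(ct$cell_line)
  if (length(cls) > 1) {
    out <- lapply(cls, function(cl)
      relative_expression_ddct(ct[ct$cell_line == cl, , drop = FALSE],
                               target, reference, calibrator))
    names(out) <- cls
    return(out)
  }
  tgt <- ct[ct$gene == target, , drop = FALSE]
  ref <- ct[ct$gene == reference, , drop = FALSE]
  if (!nrow(tgt)) stop("no rows for target gene '", target, "'")
  if (!nrow(ref)) stop("no rows for reference gene '", reference, "'")
  key <- function(d) paste(d$time_h, d$replicate, d$experiment, sep = "|")
  ref_ct <- ref$ct[match(key(tgt), key(ref))]
  if (anyNA(ref_ct)) {
    orphan <- tgt[which(is.na(ref_ct))[1], ]
    stop(sprintf(
      "no reference (%s) Ct matching target row cell_line=%s time_h=%g replicate=%s experiment=%s",
      reference, orphan$cell_line, orphan$time_h, orphan$replicate, orphan$experiment))
  }
  d <- data.frame(time = tgt$time_h,
                  rep_id = paste(tgt$replicate, tgt$experiment, sep = "."),
                  dct = tgt$ct - ref_ct, stringsAsFactors = FALSE)
  cal <- switch(calibrator,
                t0 = {
                  t0 <- min(d$time)
                  at0 <- d[d$time == t0, ]
                  v <- at0$dct[match(d$rep_id, at0$rep_id)]
                  if (anyNA(v))
                    stop("calibrator 't0' needs a t = ", t0,
                         " h observation in every replicate")
                  v
                },
                mean = stats::ave(d$dct, d$rep_id))
  d$value <- 2^(-(d$dct - cal))
  times <- sort(unique(d$time))
  reps <- sort(unique(d$rep_id))
  values <- matrix(NA_real_, length(times), length(reps),
                   dimnames = list(NULL, reps))
  values[cbind(match(d$time, times), match(d$rep_id, reps))] <- d$value
  timecourse(times, values, cell_line = cls, gene = target)
}

#' Per-replicate mean normalization
#'
#' Divides each replicate's series by that replicate's mean over its
#' present time points, giving expression relative to the replicate's
#' temporal mean (per-replicate mean exactly 1 afterwards; idempotent).
#'
#' @param tc a [timecourse] object with strictly positive values.
#' @return A [timecourse] with normalized values.
#' @export
mean_normalize <- function(tc) {
  stopifnot(inherits(tc, "timecourse"))
  mu <- colMeans(tc$values, na.rm = TRUE)
  if (any(!is.finite(mu)) )
    stop("replicate with no present values cannot be normalized")
  if (any(mu <= 0))
    stop("non-positive replicate mean in replicate(s): ",
         paste(colnames(tc$values)[mu <= 0], collapse = ", "))
  tc$values <- sweep(tc$values, 2, mu, "/")
  tc
}

#' Per-time-point replicate summaries
#'
#' Median, unbiased sample variance and replicate count at each time
#' point, skipping absent entries. Variance is `NA` (flagged) where only
#' one replicate is present; downstream weighting must handle zero or
#' undefined variances.
#'
#' @param tc a [timecourse] object.
#' @return A data.frame of class `replicate_summary` with columns
#'   `time, median, variance, n, variance_defined`.
#' @export
summarize_replicates <- function(tc) {
  stopifnot(inherits(tc, "timecourse"))
  med <- apply(tc$values, 1, stats::median, na.rm = TRUE)
  v <- apply(tc$values, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) NA_real_ else stats::var(x)
  })
  n <- rowSums(!is.na(tc$values))
  out <- data.frame(time = tc$times, median = med, variance = v, n = n,
                    variance_defined = n >= 2)
  class(out) <- c("replicate_summary", "data.frame")
  out
}

#' Collapse technical replicates by median
#'
#' qPCR designs typically run several technical replicates per biological
#' replicate; analyses assume one Ct per biological replicate. This helper
#' pre-averages (by median) technical replicates identified by a
#' `tech_replicate` column, leaving the remaining key columns unchanged.
#'
#' @param ct a `ct_table`-style data.frame with an extra `tech_replicate`
#'   column.
#' @return A `ct_table` with one row per (cell_line, gene, time_h,
#'   replicate, experiment).
#' @export
collapse_technical_replicates <- function(ct) {
  ct <- as.data.frame(ct)
  if (!"tech_replicate" %in% names(ct)) return(ct)
  keys <- c("cell_line", "gene", "time_h", "replicate", "experiment")
  keys <- intersect(keys, names(ct))
  agg <- stats::aggregate(ct["ct"], by = ct[keys], FUN = stats::median)
  class(agg) <- c("ct_table", "data.frame")
  agg
}
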