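#' Replicated expression time course
#'
#' The central data container: observations of one gene in one cell line
#' over time, with replicates. Values are held as a time-by-replicate
#' matrix in which `NA` marks an absent (dropped) observation. Every time
#' point must retain at least one present observation.
#'
#' @param times strictly increasing numeric vector of sampling times (h).
#' @param values numeric matrix with `length(times)` rows; columns are
#'   replicates; `NA` entries are absent observations.
#' @param cell_line,gene identifiers carried through the pipeline.
#' @param units unit label (default `"relative expression"`).
#' @param experiment optional vector of experiment labels, one per
#'   replicate column (batch bookkeeping only).
#'
#' @return An object of class `timecourse`.
#' @export
timecourse <- function(times, values, cell_line = "unknown", gene = "unknown",
                       units = "relative expression", experiment = NULL) {
  times <- as.numeric(times)
  values <- as.matrix(values)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (nrow(values) != length(times))
    stop("nrow(values) must equal length(times)")
  n_present <- rowSums(!is.na(values))
  if (any(n_present < 1))
    stop("every time point needs at least one present observation; empty at t = ",
         paste(times[n_present < 1], collapse = ", "))
  if (any(!is.finite(values[!is.na(values)])))
    stop("all present values must be finite")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("rep", seq_len(ncol(values)))
  if (!is.null(experiment) && length(experiment) != ncol(values))
    stop("'experiment' must have one entry per replicate column")
  structure(list(cell_line = cell_line, gene = gene, times = times,
                 values = values, units = units, experiment = experiment),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("<timecourse> %s / %s: %d time points (%g-%g h), %d replicates, %d absent\n",
              x$cell_line, x$gene, length(x$times), min(x$times), max(x$times),
              ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Flatten a timecourse to long (time, replicate, value) points
#'
#' Absent entries are dropped. Used internally by every test and fit:
#' replicates enter all analyses as independent observations at their
#' time points.
#'
#' @param tc a [timecourse] object.
#' @return A data.frame with columns `time`, `replicate`, `value`.
#' @export
tc_points <- function(tc) {
  stopifnot(inherits(tc, "timecourse"))
  idx <- which(!is.na(tc$values), arr.ind = TRUE)
  data.frame(time = tc$times[idx[, 1]],
             replicate = colnames(tc$values)[idx[, 2]],
             value = tc$values[idx],
             stringsAsFactors = FALSE)[order(idx[, 1], idx[, 2]), ]
}

#' @rdname timecourse
#' @param x object to test.
#' @export
is_timecourse <- function(x) inherits(x, "timecourse")

tc_label <- function(tc) paste(tc$cell_line, tc$gene, sep = ":")
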