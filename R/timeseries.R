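#' Construct a parcellated time-series matrix
#'
#' The core data container: an `N x L` numeric matrix, one row per region
#' (parcel) and one column per timepoint, with unique region identifiers as
#' row names. This is the in-memory orientation; on disk the transpose is
#' stored (rows = timepoints, see [read_timeseries()]).
#'
#' @param values numeric matrix, regions x timepoints (`N x L`, `L >= 2`),
#'   all values finite.
#' @param region_ids character vector of unique region identifiers, length
#'   `N`. Defaults to existing row names, or `R1..RN`.
#' @param sampling_interval optional positive scalar, seconds per timepoint
#'   (the fMRI TR). Metadata only; no computation depends on it.
#' @return a `brainrev_ts` object (a numeric matrix with attributes).
#' @examples
#' ts <- timeseries_matrix(matrix(rnorm(300), nrow = 3))
#' dim(ts)
#' @export
timeseries_matrix <- function(values, region_ids = NULL, sampling_interval = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (regions x timepoints)", call. = FALSE)
  }
  if (ncol(values) < 2L) {
    stop("time series must have at least 2 timepoints, got ", ncol(values), call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at region row %d, timepoint %d", bad[1L], bad[2L]),
         call. = FALSE)
  }
  if (is.null(region_ids)) {
    region_ids <- rownames(values)
    if (is.null(region_ids)) region_ids <- paste0("R", seq_len(nrow(values)))
  }
  region_ids <- as.character(region_ids)
  if (length(region_ids) != nrow(values)) {
    stop("length(region_ids) must equal nrow(values)", call. = FALSE)
  }
  if (anyDuplicated(region_ids)) {
    stop("region ids must be unique; duplicated: ",
         paste(unique(region_ids[duplicated(region_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(sampling_interval)) {
    stopifnot(is.numeric(sampling_interval), length(sampling_interval) == 1L,
              sampling_interval > 0)
  }
  rownames(values) <- region_ids
  structure(values,
            sampling_interval = sampling_interval,
            class = c("brainrev_ts", "matrix", "array"))
}

#' @export
print.brainrev_ts <- function(x, ...) {
  cat(sprintf("<brainrev_ts> %d regions x %d timepoints\n", nrow(x), ncol(x)))
  tr <- attr(x, "sampling_interval")
  if (!is.null(tr)) cat(sprintf("  sampling interval: %g s\n", tr))
  invisible(x)
}

as_timeseries <- function(ts) {
  if (inherits(ts, "brainrev_ts")) return(ts)
  timeseries_matrix(as.matrix(ts))
}

#' Reverse the time axis of a series
#'
#' Flips the temporal ordering of every region's signal, producing the
#' time-reversed surrogate against which forward causal structure is
#' compared. Region order, ids and metadata are unchanged; applying it twice
#' restores the input exactly.
#'
#' @param ts a [timeseries_matrix()].
#' @return a `brainrev_ts` with each row reversed in time.
#' @export
time_reverse <- function(ts) {
  ts <- as_timeseries(ts)
  out <- ts[, ncol(ts):1L, drop = FALSE]
  attributes(out) <- attributes(ts)
  out
}
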