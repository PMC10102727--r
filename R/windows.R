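#' Sliding-window scheme
#'
#' Window length `W` and overlap between consecutive windows, both in
#' timepoints; the step is `W - overlap`. Defaults are 90-point windows
#' overlapping by 85 points (step 5), the parameters used throughout the
#' analysis.
#'
#' @param window_length positive integer `W`.
#' @param overlap nonnegative integer `< W`.
#' @return a `brainrev_windowing` list with fields `window_length`, `overlap`,
#'   `step`.
#' @export
windowing_scheme <- function(window_length = 90L, overlap = 85L) {
  window_length <- as.integer(window_length)
  overlap <- as.integer(overlap)
  if (window_length < 1L) stop("window_length must be positive", call. = FALSE)
  if (overlap < 0L || overlap >= window_length) {
    stop("overlap must satisfy 0 <= overlap < window_length", call. = FALSE)
  }
  structure(list(window_length = window_length, overlap = overlap,
                 step = window_length - overlap),
            class = "brainrev_windowing")
}

#' @export
print.brainrev_windowing <- function(x, ...) {
  cat(sprintf("<windowing> W = %d, overlap = %d, step = %d\n",
              x$window_length, x$overlap, x$step))
  invisible(x)
}

#' Enumerate sliding windows over a series of length L
#'
#' Returns the start/end columns (1-based, inclusive) of each counted window.
#' The count convention is `n = floor((L - W) / step)`: window `k`
#' (`k = 0..n-1`) covers timepoints `k*step + 1 .. k*step + W`, and the last
#' admissible window is deliberately dropped. This convention — not the usual
#' `floor((L - W)/step) + 1` — is forced by the reference window counts it
#' must reproduce (21 windows for L = 195 and 17 for L = 175 at W = 90,
#' step 5). `include_final_window = TRUE` restores the +1 convention.
#'
#' @param L series length in timepoints, `L > W`.
#' @param scheme a [windowing_scheme()].
#' @param include_final_window keep the final admissible window (default
#'   `FALSE`).
#' @return data.frame with columns `window` (0-based index), `start`, `end`.
#' @export
make_windows <- function(L, scheme = windowing_scheme(), include_final_window = FALSE) {
  L <- as.integer(L)
  W <- scheme$window_length
  step <- scheme$step
  if (L <= W) {
    stop(sprintf("series too short: L = %d <= window length %d", L, W), call. = FALSE)
  }
  n <- (L - W) %/% step
  if (include_final_window) n <- n + 1L
  k <- seq_len(n) - 1L
  data.frame(window = k, start = k * step + 1L, end = k * step + W)
}

#' Per-subject sliding-window reversibility profile
#'
#' Evaluates [global_irreversibility()] in every sliding window and
#' summarizes the subject by the mean of the per-window values ("average
#' reversibility") and their sample standard deviation, n-1 denominator
#' ("deviation reversibility", the non-stationarity of the asymmetry).
#'
#' @inheritParams global_irreversibility
#' @param scheme a [windowing_scheme()].
#' @param subject_id optional identifier carried into the result.
#' @param include_final_window see [make_windows()].
#' @return a `brainrev_profile` list: `subject_id`, `values` (per-window I),
#'   `average_reversibility`, `deviation_reversibility`, `n_windows`,
#'   `windows` (the window table).
#' @export
subject_profile <- function(ts, scheme = windowing_scheme(), shift = 1L,
                            estimator = c("segment_normalized", "full_window"),
                            zero_variance_policy = c("error", "zero"),
                            exclude_diagonal = FALSE,
                            include_final_window = FALSE,
                            subject_id = NA_character_) {
  estimator <- match.arg(estimator)
  zero_variance_policy <- match.arg(zero_variance_policy)
  ts <- as_timeseries(ts)
  win <- make_windows(ncol(ts), scheme, include_final_window)
  if (nrow(win) < 2L) {
    stop("need at least 2 windows for a deviation; got ", nrow(win), call. = FALSE)
  }
  vals <- vapply(seq_len(nrow(win)), function(k) {
    global_irreversibility(ts[, win$start[k]:win$end[k], drop = FALSE],
                           shift, estimator, zero_variance_policy, exclude_diagonal)
  }, numeric(1))
  structure(list(subject_id = subject_id,
                 values = vals,
                 average_reversibility = mean(vals),
                 deviation_reversibility = stats::sd(vals),
                 n_windows = length(vals),
                 windows = win),
            class = "brainrev_profile")
}

#' @export
print.brainrev_profile <- function(x, ...) {
  cat(sprintf("<subject profile> %s: %d windows, average = %.4g, deviation = %.4g\n",
              x$subject_id, x$n_windows,
              x$average_reversibility, x$deviation_reversibility))
  invisible(x)
}
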