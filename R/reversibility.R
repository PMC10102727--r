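# r^2 is clipped at 1 - MI_CLIP before the log so perfectly correlated pairs
# give a large finite value instead of Inf.
MI_CLIP <- 1e-12

#' Time-shifted Pearson correlation of two signals
#'
#' Sample Pearson correlation of the `L - shift` pairs
#' `(x(t), y(t + shift))`, `t = 1..L-shift`. Under the default
#' `"segment_normalized"` estimator, means and standard deviations are those
#' of the two overlapping segments themselves (ordinary [stats::cor()] on the
#' lagged pair); `shift = 0` is plain Pearson correlation. The
#' `"full_window"` estimator instead centres and scales each signal by its
#' full-window mean and (population) standard deviation, which differs from
#' the segment-normalized value by edge terms of order `1/L`.
#'
#' @param x,y numeric vectors of equal length `L`.
#' @param shift nonnegative integer lag; requires `L - shift >= 3`.
#' @param estimator `"segment_normalized"` (default) or `"full_window"`.
#' @param zero_variance_policy `"error"` (default) raises on a zero-variance
#'   segment; `"zero"` returns 0 with a warning.
#' @return correlation in `[-1, 1]`.
#' @export
shifted_pearson <- function(x, y, shift,
                            estimator = c("segment_normalized", "full_window"),
                            zero_variance_policy = c("error", "zero")) {
  estimator <- match.arg(estimator)
  zero_variance_policy <- match.arg(zero_variance_policy)
  x <- as.numeric(x); y <- as.numeric(y)
  L <- length(x)
  if (length(y) != L) stop("x and y must have equal length", call. = FALSE)
  shift <- as.integer(shift)
  if (shift < 0L) stop("shift must be nonnegative", call. = FALSE)
  if (L - shift < 3L) {
    stop(sprintf("need L - shift >= 3 overlapping pairs (L = %d, shift = %d)", L, shift),
         call. = FALSE)
  }
  xs <- x[seq_len(L - shift)]
  ys <- y[seq.int(1L + shift, L)]
  if (estimator == "segment_normalized") {
    vx <- stats::var(xs); vy <- stats::var(ys)
    if (vx <= 0 || vy <= 0) {
      return(.degenerate(zero_variance_policy, "zero-variance segment in shifted_pearson"))
    }
    r <- stats::cor(xs, ys)
  } else {
    mx <- mean(x); my <- mean(y)
    sx <- sqrt(mean((x - mx)^2)); sy <- sqrt(mean((y - my)^2))
    if (sx <= 0 || sy <= 0) {
      return(.degenerate(zero_variance_policy, "zero-variance window in shifted_pearson"))
    }
    r <- mean((xs - mx) * (ys - my)) / (sx * sy)
    r <- min(1, max(-1, r))
  }
  r
}

.degenerate <- function(policy, msg) {
  if (policy == "error") stop(msg, call. = FALSE)
  warning(msg, "; returning 0", call. = FALSE)
  0
}

#' Pairwise irreversibility of two signals
#'
#' The absolute difference between the lag-`shift` correlation of the forward
#' signals and that of their explicitly time-reversed versions,
#' `|c_forward(T) - c_reversed(T)|`. Correlations keep their signs; only the
#' difference is taken in absolute value. Zero for any pair whose forward and
#' reversed lagged dependence coincide (e.g. `x == y`), and invariant to
#' reversing both inputs.
#'
#' @inheritParams shifted_pearson
#' @return nonnegative real.
#' @export
pairwise_irreversibility <- function(x, y, shift = 1L,
                                     estimator = c("segment_normalized", "full_window"),
                                     zero_variance_policy = c("error", "zero")) {
  estimator <- match.arg(estimator)
  zero_variance_policy <- match.arg(zero_variance_policy)
  cf <- shifted_pearson(x, y, shift, estimator, zero_variance_policy)
  cr <- shifted_pearson(rev(x), rev(y), shift, estimator, zero_variance_policy)
  abs(cf - cr)
}

#' Gaussian mutual information of a correlation coefficient
#'
#' `-1/2 * log(1 - r^2)` (nats), the mutual information of a bivariate
#' Gaussian with correlation `r`. Even in `r`, strictly increasing in `|r|`,
#' zero at `r = 0`. `r^2` is clipped at `1 - 1e-12` before the log, so
#' `|r| = 1` maps to about 13.8155 nats rather than infinity.
#'
#' @param r numeric vector of correlations in `[-1, 1]` (values beyond 1 by
#'   more than 1e-8 are a domain error; tiny numerical excursions are
#'   clamped).
#' @return nonnegative mutual information values, nats.
#' @export
mutual_info_of_correlation <- function(r) {
  if (!is.numeric(r)) stop("r must be numeric", call. = FALSE)
  if (any(abs(r) > 1 + 1e-8, na.rm = TRUE)) {
    stop("correlation outside [-1, 1]: ", max(abs(r)), call. = FALSE)
  }
  -0.5 * log(pmax(1 - r^2, MI_CLIP))
}

# Row-standardize the two lagged segment matrices and return the N x N
# correlation matrix C[i, j] = cor(x_i(t), x_j(t + shift)) in one tcrossprod.
.lagged_cor_matrix <- function(values, shift, estimator, zero_variance_policy) {
  L <- ncol(values)
  n <- L - shift
  A <- values[, seq_len(n), drop = FALSE]
  B <- values[, seq.int(1L + shift, L), drop = FALSE]
  if (estimator == "segment_normalized") {
    A <- A - rowMeans(A)
    B <- B - rowMeans(B)
    sa <- sqrt(rowSums(A^2))
    sb <- sqrt(rowSums(B^2))
  } else {
    m <- rowMeans(values)
    s <- sqrt(rowMeans((values - m)^2))
    A <- A - m
    B <- B - m
    sa <- s * sqrt(n)
    sb <- sa
  }
  bad <- which(sa <= 0 | sb <= 0)
  if (length(bad)) {
    msg <- paste0("zero-variance segment for region(s): ",
                  paste(rownames(values)[bad], collapse = ", "))
    if (zero_variance_policy == "error") stop(msg, call. = FALSE)
    warning(msg, "; correlations set to 0", call. = FALSE)
    sa[bad] <- Inf
    sb[bad] <- Inf
  }
  C <- tcrossprod(A / sa, B / sb)
  # numerical guard: |r| can exceed 1 by machine epsilon
  C[C > 1] <- 1
  C[C < -1] <- -1
  C
}

#' Functional-shift (FS) matrix of a multivariate series
#'
#' The `N x N` matrix whose `(i, j)` entry is the Gaussian mutual information
#' of the lag-`shift` Pearson correlation between region `i` at time `t` and
#' region `j` at time `t + shift`. For `direction = "reversal"` every row is
#' first time-reversed, yielding the FS matrix of the backward evolution. The
#' matrix is not symmetric in general: directed temporal dependence makes
#' `(i, j)` and `(j, i)` differ.
#'
#' Under the `"segment_normalized"` estimator the reversal matrix equals the
#' transpose of the forward matrix exactly (reversing both series enumerates
#' the same lagged pairs with roles exchanged); the reversal is nevertheless
#' always computed from the flipped series.
#'
#' @param ts a [timeseries_matrix()].
#' @param shift nonnegative integer lag `T` (default 1).
#' @param direction `"forward"` or `"reversal"`.
#' @inheritParams shifted_pearson
#' @return a `brainrev_fs` matrix (nats) with attributes `shift` and
#'   `direction`.
#' @export
fs_matrix <- function(ts, shift = 1L, direction = c("forward", "reversal"),
                      estimator = c("segment_normalized", "full_window"),
                      zero_variance_policy = c("error", "zero")) {
  direction <- match.arg(direction)
  estimator <- match.arg(estimator)
  zero_variance_policy <- match.arg(zero_variance_policy)
  ts <- as_timeseries(ts)
  shift <- as.integer(shift)
  if (shift < 0L) stop("shift must be nonnegative", call. = FALSE)
  if (ncol(ts) - shift < 3L) {
    stop(sprintf("need L - shift >= 3 (L = %d, shift = %d)", ncol(ts), shift),
         call. = FALSE)
  }
  if (direction == "reversal") ts <- time_reverse(ts)
  C <- .lagged_cor_matrix(unclass(ts), shift, estimator, zero_variance_policy)
  FS <- mutual_info_of_correlation(C)
  dimnames(FS) <- list(rownames(ts), rownames(ts))
  structure(FS, shift = shift, direction = direction,
            class = c("brainrev_fs", "matrix", "array"))
}

#' Reversibility matrix: squared forward/reversal FS difference
#'
#' Elementwise `(FS_forward - FS_reversal)^2`. All entries are nonnegative;
#' the diagonal is zero (a region's forward and reversed lagged
#' autocorrelation coincide), and under the segment-normalized estimator the
#' matrix is symmetric.
#'
#' @param fs_f forward [fs_matrix()].
#' @param fs_r reversal [fs_matrix()] of the same series, shape and shift.
#' @return a `brainrev_revmat` matrix (nats^2) with attribute `shift`.
#' @export
reversibility_matrix <- function(fs_f, fs_r) {
  if (!inherits(fs_f, "brainrev_fs") || !inherits(fs_r, "brainrev_fs")) {
    stop("inputs must be fs_matrix() results", call. = FALSE)
  }
  if (!identical(dim(fs_f), dim(fs_r))) stop("FS matrices differ in shape", call. = FALSE)
  if (!identical(attr(fs_f, "shift"), attr(fs_r, "shift"))) {
    stop("FS matrices differ in shift", call. = FALSE)
  }
  if (attr(fs_f, "direction") != "forward" || attr(fs_r, "direction") != "reversal") {
    stop("expected a forward and a reversal FS matrix, in that order", call. = FALSE)
  }
  D <- (unclass(fs_f) - unclass(fs_r))^2
  structure(D, shift = attr(fs_f, "shift"),
            class = c("brainrev_revmat", "matrix", "array"))
}

#' Global irreversibility of a multivariate series
#'
#' The squared distance `I = || FS_forward(T) - FS_reversal(T) ||_2`, where
#' the norm is the mean of the squared elements: the mean over all `N^2`
#' entries (diagonal included by default) of the reversibility matrix. Zero
#' for processes in detailed balance (up to sampling noise); invariant to
#' region permutation, to per-region affine rescaling with positive slope,
#' and to time-reversal of the input.
#'
#' @inheritParams fs_matrix
#' @param exclude_diagonal if `TRUE`, average off-diagonal entries only
#'   (default `FALSE`: all `N^2` elements, matching the norm's definition;
#'   the diagonal is ~0 either way).
#' @return nonnegative scalar (nats^2).
#' @export
global_irreversibility <- function(ts, shift = 1L,
                                   estimator = c("segment_normalized", "full_window"),
                                   zero_variance_policy = c("error", "zero"),
                                   exclude_diagonal = FALSE) {
  estimator <- match.arg(estimator)
  zero_variance_policy <- match.arg(zero_variance_policy)
  ts <- as_timeseries(ts)
  D <- reversibility_matrix(
    fs_matrix(ts, shift, "forward", estimator, zero_variance_policy),
    fs_matrix(ts, shift, "reversal", estimator, zero_variance_policy)
  )
  if (exclude_diagonal) {
    n <- nrow(D)
    if (n == 1L) return(0)
    (sum(D) - sum(diag(D))) / (n * (n - 1L))
  } else {
    mean(D)
  }
}
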