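#' Within- or between-network irreversibility
#'
#' The reversibility statistic restricted to a pair of node sets: the mean of
#' the squared forward/reversal FS differences over the `|A| x |B|` block
#' whose rows are the regions of `net_a` and whose columns are the regions of
#' `net_b` (within-network when `net_a == net_b`, diagonal included). Each FS
#' entry depends only on its own row pair, so restricting the global matrices
#' to the block is identical to recomputing the statistic on the subset of
#' nodes. Symmetric in `(net_a, net_b)`.
#'
#' @inheritParams global_irreversibility
#' @param atlas a [parcel_atlas()] matching the series regions in order.
#' @param net_a,net_b network labels present in the atlas.
#' @return nonnegative scalar (nats^2).
#' @export
submatrix_irreversibility <- function(ts, atlas, net_a, net_b, shift = 1L,
                                      estimator = c("segment_normalized", "full_window"),
                                      zero_variance_policy = c("error", "zero")) {
  estimator <- match.arg(estimator)
  zero_variance_policy <- match.arg(zero_variance_policy)
  ts <- as_timeseries(ts)
  idx <- .atlas_indices(atlas, rownames(ts))
  for (lab in c(net_a, net_b)) {
    if (!lab %in% names(idx)) stop("unknown network label: ", lab, call. = FALSE)
  }
  D <- reversibility_matrix(
    fs_matrix(ts, shift, "forward", estimator, zero_variance_policy),
    fs_matrix(ts, shift, "reversal", estimator, zero_variance_policy)
  )
  mean(D[idx[[net_a]], idx[[net_b]], drop = FALSE])
}

.network_pairs <- function(labels) {
  # unordered pairs (a, b) with a at or after b in the canonical ordering:
  # diagonal = within-network, below-diagonal = between-network
  labels <- CANONICAL_NETWORKS[CANONICAL_NETWORKS %in% labels]
  n <- length(labels)
  pairs <- expand.grid(b = seq_len(n), a = seq_len(n))
  pairs <- pairs[pairs$a >= pairs$b, c("a", "b")]
  data.frame(net_a = labels[pairs$a], net_b = labels[pairs$b],
             stringsAsFactors = FALSE)
}

#' Per-subject network-level reversibility profile
#'
#' For every unordered pair of networks in the atlas, evaluates the block
#' reversibility statistic in each sliding window, then summarizes across
#' windows by mean ("average") and sample standard deviation ("deviation").
#' With the seven canonical networks this fills a 7 x 7 lower-triangular
#' matrix (diagonal = within-network) per summary.
#'
#' @inheritParams subject_profile
#' @param atlas a [parcel_atlas()] matching the series regions in order.
#' @return a `brainrev_network_profile` list: `subject_id`, `pairs` (long
#'   data.frame with `net_a`, `net_b`, `average`, `deviation`), `values`
#'   (pairs x windows matrix of per-window block statistics), `average` and
#'   `deviation` (lower-triangular named matrices, NA above the diagonal),
#'   `n_windows`.
#' @export
network_profile <- function(ts, atlas, scheme = windowing_scheme(), shift = 1L,
                            estimator = c("segment_normalized", "full_window"),
                            zero_variance_policy = c("error", "zero"),
                            include_final_window = FALSE,
                            subject_id = NA_character_) {
  estimator <- match.arg(estimator)
  zero_variance_policy <- match.arg(zero_variance_policy)
  ts <- as_timeseries(ts)
  idx <- .atlas_indices(atlas, rownames(ts))
  labels <- names(idx)
  pairs <- .network_pairs(labels)
  win <- make_windows(ncol(ts), scheme, include_final_window)
  if (nrow(win) < 2L) {
    stop("need at least 2 windows for a deviation; got ", nrow(win), call. = FALSE)
  }
  vals <- matrix(NA_real_, nrow(pairs), nrow(win))
  for (k in seq_len(nrow(win))) {
    seg <- ts[, win$start[k]:win$end[k], drop = FALSE]
    D <- reversibility_matrix(
      fs_matrix(seg, shift, "forward", estimator, zero_variance_policy),
      fs_matrix(seg, shift, "reversal", estimator, zero_variance_policy)
    )
    for (p in seq_len(nrow(pairs))) {
      vals[p, k] <- mean(D[idx[[pairs$net_a[p]]], idx[[pairs$net_b[p]]], drop = FALSE])
    }
  }
  pairs$average <- rowMeans(vals)
  pairs$deviation <- apply(vals, 1L, stats::sd)
  ord <- CANONICAL_NETWORKS[CANONICAL_NETWORKS %in% labels]
  tri <- function(col) {
    m <- matrix(NA_real_, length(ord), length(ord), dimnames = list(ord, ord))
    m[cbind(match(pairs$net_a, ord), match(pairs$net_b, ord))] <- col
    m
  }
  structure(list(subject_id = subject_id, pairs = pairs, values = vals,
                 average = tri(pairs$average), deviation = tri(pairs$deviation),
                 n_windows = nrow(win)),
            class = "brainrev_network_profile")
}

#' @export
print.brainrev_network_profile <- function(x, ...) {
  cat(sprintf("<network profile> %s: %d network pairs x %d windows\n",
              x$subject_id, nrow(x$pairs), x$n_windows))
  invisible(x)
}
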