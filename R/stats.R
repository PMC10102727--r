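#' Mann-Whitney U (Wilcoxon rank-sum) test
#'
#' Two-sided test of stochastic equality of two samples. When both samples
#' have at most 8 observations and there are no ties across the pooled data,
#' the exact null distribution of U is used; otherwise a normal approximation
#' with midranks, tie-corrected variance and continuity correction.
#'
#' @param a,b nonempty numeric vectors.
#' @return list with `U` (the U statistic of sample `a`: the number of pairs
#'   `(a_i, b_j)` with `a_i > b_j`, ties counted 1/2), `p` (two-sided),
#'   `method` (`"exact"` or `"normal"`).
#' @export
ranksum_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be nonempty", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("NA values not allowed", call. = FALSE)
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && m <= 8L && n <= 8L) {
    # exact null distribution of U (no ties)
    p <- min(1, 2 * min(stats::pwilcox(U, m, n),
                        1 - stats::pwilcox(U - 1, m, n)))
    list(U = U, p = p, method = "exact")
  } else {
    N <- m + n
    mu <- m * n / 2
    tie_tab <- table(pooled)
    sigma2 <- (m * n / 12) * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
    cc <- sign(U - mu) * 0.5
    z <- (U - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(U = U, p = p, method = "normal")
  }
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sort ascending, multiply the k-th by `m / k`,
#' enforce monotonicity from the largest down (running minimum), cap at 1,
#' restore the input order. Output is elementwise at least the input.
#'
#' @param p numeric vector of raw p-values in `(0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  # a*m/k can undershoot a by one ulp when k = m; the adjusted value is
  # mathematically never below the raw one, so enforce it
  q <- pmin(pmax(q, p[ord]), 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Global-level group comparisons
#'
#' Rank-sum tests of every unordered pair of groups, separately for average
#' and deviation reversibility, each measure forming its own
#' Benjamini-Hochberg family (3 tests per family in a three-group design).
#'
#' @param profiles data.frame with columns `subject_id`, `group`,
#'   `average_reversibility`, `deviation_reversibility` (one row per subject;
#'   see [profiles_table()]).
#' @param alpha significance threshold recorded in the output (default 0.01).
#' @return data.frame, one row per (group pair, measure): `group_a`,
#'   `group_b`, `measure`, `U`, `p_raw`, `p_fdr`, `significant`.
#' @export
compare_global <- function(profiles, alpha = 0.01) {
  need <- c("subject_id", "group", "average_reversibility", "deviation_reversibility")
  if (!all(need %in% names(profiles))) {
    stop("profiles must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  groups <- unique(profiles$group)
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  sizes <- table(profiles$group)
  if (any(sizes < 2L)) {
    stop("every group needs >= 2 subjects; offending: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  pairs <- utils::combn(groups, 2L)
  measures <- c(average = "average_reversibility", deviation = "deviation_reversibility")
  res <- list()
  for (mi in seq_along(measures)) {
    rows <- lapply(seq_len(ncol(pairs)), function(k) {
      ga <- pairs[1L, k]; gb <- pairs[2L, k]
      t <- ranksum_test(profiles[profiles$group == ga, measures[[mi]]],
                        profiles[profiles$group == gb, measures[[mi]]])
      data.frame(group_a = ga, group_b = gb, measure = names(measures)[mi],
                 U = t$U, p_raw = t$p, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    tab$p_fdr <- bh_adjust(tab$p_raw)   # family = the pairwise tests of one measure
    res[[mi]] <- tab
  }
  out <- do.call(rbind, res)
  out$significant <- out$p_fdr < alpha
  rownames(out) <- NULL
  out
}

#' Network-level group comparisons
#'
#' For each group pair and measure, one rank-sum test per unordered network
#' pair (28 with seven networks: 7 within + 21 between). Two FDR families are
#' computed and both reported: `p_fdr_within` corrects the 7 within-network
#' tests only (the family behind per-network summaries) and `p_fdr_all`
#' corrects all 28 (the family behind the triangular significance matrices).
#'
#' @param net_profiles long data.frame with columns `subject_id`, `group`,
#'   `net_a`, `net_b`, `average`, `deviation` (one row per subject x network
#'   pair; see [network_profiles_table()]).
#' @param alpha threshold used for the binarized triangles (default 0.01).
#' @return list with `results` (long data.frame incl. `p_fdr_within`,
#'   `p_fdr_all`) and `triangles`: per group pair and measure, lower
#'   triangular matrices `p_fdr` (the 28-family) and `binarized`.
#' @export
compare_networks <- function(net_profiles, alpha = 0.01) {
  need <- c("subject_id", "group", "net_a", "net_b", "average", "deviation")
  if (!all(need %in% names(net_profiles))) {
    stop("net_profiles must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  groups <- unique(net_profiles$group)
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  gpairs <- utils::combn(groups, 2L)
  netkey <- unique(net_profiles[, c("net_a", "net_b")])
  ord <- CANONICAL_NETWORKS[CANONICAL_NETWORKS %in%
                              unique(c(netkey$net_a, netkey$net_b))]
  results <- list()
  triangles <- list()
  for (k in seq_len(ncol(gpairs))) {
    ga <- gpairs[1L, k]; gb <- gpairs[2L, k]
    for (measure in c("average", "deviation")) {
      rows <- lapply(seq_len(nrow(netkey)), function(i) {
        sel <- net_profiles$net_a == netkey$net_a[i] &
          net_profiles$net_b == netkey$net_b[i]
        va <- net_profiles[sel & net_profiles$group == ga, measure]
        vb <- net_profiles[sel & net_profiles$group == gb, measure]
        t <- ranksum_test(va, vb)
        data.frame(group_a = ga, group_b = gb, measure = measure,
                   net_a = netkey$net_a[i], net_b = netkey$net_b[i],
                   U = t$U, p_raw = t$p, stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, rows)
      within <- tab$net_a == tab$net_b
      tab$p_fdr_within <- NA_real_
      tab$p_fdr_within[within] <- bh_adjust(tab$p_raw[within])
      tab$p_fdr_all <- bh_adjust(tab$p_raw)
      results[[length(results) + 1L]] <- tab
      tri <- matrix(NA_real_, length(ord), length(ord), dimnames = list(ord, ord))
      tri[cbind(match(tab$net_a, ord), match(tab$net_b, ord))] <- tab$p_fdr_all
      key <- sprintf("%s_vs_%s.%s", ga, gb, measure)
      triangles[[key]] <- list(p_fdr = tri,
                               binarized = binarize_significance(tri, alpha))
    }
  }
  list(results = do.call(rbind, results), triangles = triangles)
}

#' Binarize a significance triangle
#'
#' @param triangle matrix of FDR-corrected p-values (NA above the diagonal).
#' @param alpha threshold in `(0, 1)`; a cell is 1 iff `p_fdr < alpha`.
#' @return matrix of 0/1 (NA cells stay NA).
#' @export
binarize_significance <- function(triangle, alpha = 0.01) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("alpha must be in (0, 1]", call. = FALSE)
  }
  out <- triangle
  out[] <- as.numeric(triangle < alpha)
  out
}
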