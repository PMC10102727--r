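# The seven canonical resting-state network labels (Yeo ordering).
CANONICAL_NETWORKS <- c("Visual", "Somatomotor", "DorsalAttention",
                        "VentralAttention", "Limbic", "Control", "Default")

#' Construct a parcel atlas
#'
#' Maps each region to exactly one resting-state network. Labels must come
#' from the seven canonical network names (`Visual`, `Somatomotor`,
#' `DorsalAttention`, `VentralAttention`, `Limbic`, `Control`, `Default`).
#'
#' @param region_ids character vector of unique region ids.
#' @param network character vector, same length, of network labels.
#' @return a `brainrev_atlas` data.frame with columns `region_id`, `network`.
#' @export
parcel_atlas <- function(region_ids, network) {
  region_ids <- as.character(region_ids)
  network <- as.character(network)
  if (length(region_ids) != length(network)) {
    stop("region_ids and network must have equal length", call. = FALSE)
  }
  if (anyDuplicated(region_ids)) stop("region ids must be unique", call. = FALSE)
  unknown <- setdiff(unique(network), CANONICAL_NETWORKS)
  if (length(unknown)) {
    stop("unknown network label(s): ", paste(unknown, collapse = ", "),
         "; expected one of ", paste(CANONICAL_NETWORKS, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(region_id = region_ids, network = network,
                    stringsAsFactors = FALSE)
  class(out) <- c("brainrev_atlas", "data.frame")
  out
}

#' Default contiguous-block atlas
#'
#' Partitions `n_regions` regions into `n_networks` contiguous blocks whose
#' sizes differ by at most one (larger blocks first); block `k` receives the
#' `k`-th canonical network label. A stand-in for an anatomically derived
#' parcel-to-network assignment: `make_default_atlas(100, 7)` gives block
#' sizes 15, 15, 14, 14, 14, 14, 14.
#'
#' @param n_regions positive integer.
#' @param n_networks integer in `1..7`, at most `n_regions`.
#' @return a [parcel_atlas()].
#' @export
make_default_atlas <- function(n_regions, n_networks = 7L) {
  n_regions <- as.integer(n_regions)
  n_networks <- as.integer(n_networks)
  if (n_regions < 1L) stop("n_regions must be positive", call. = FALSE)
  if (n_networks < 1L || n_networks > 7L) {
    stop("n_networks must be in 1..7", call. = FALSE)
  }
  if (n_networks > n_regions) {
    stop(sprintf("invalid partition: n_networks (%d) > n_regions (%d)",
                 n_networks, n_regions), call. = FALSE)
  }
  base <- n_regions %/% n_networks
  extra <- n_regions %% n_networks
  sizes <- rep(base, n_networks) + c(rep(1L, extra), rep(0L, n_networks - extra))
  parcel_atlas(paste0("R", seq_len(n_regions)),
               rep(CANONICAL_NETWORKS[seq_len(n_networks)], times = sizes))
}

.atlas_indices <- function(atlas, region_ids) {
  if (!identical(atlas$region_id, as.character(region_ids))) {
    stop("atlas region ids do not match the series region ids (order matters)",
         call. = FALSE)
  }
  split(seq_along(region_ids), atlas$network)
}
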