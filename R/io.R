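# On-disk orientation: rows = timepoints, columns = regions (long,
# human-diffable); in memory the transpose (regions x timepoints) is used.

#' Read a parcellated time-series TSV
#'
#' Expects a tab-separated file with a header row of region ids, one column
#' per region and one row per timepoint. Values must be numeric and finite.
#'
#' @param path file path.
#' @return a [timeseries_matrix()].
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (!ncol(df)) stop("no columns in ", path, call. = FALSE)
  ids <- colnames(df)
  if (anyDuplicated(ids)) {
    stop("duplicate region ids in header of ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  m <- suppressWarnings(matrix(as.numeric(as.matrix(df)), nrow = nrow(df)))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric or missing value in %s at data row %d, column '%s'",
                 path, bad[1L], ids[bad[2L]]), call. = FALSE)
  }
  if (!all(is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value in %s at data row %d, column '%s'",
                 path, bad[1L], ids[bad[2L]]), call. = FALSE)
  }
  timeseries_matrix(t(m), region_ids = ids)
}

#' Write a time-series TSV
#'
#' Inverse of [read_timeseries()]: one row per timepoint, header = region ids,
#' full double precision.
#'
#' @param ts a [timeseries_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  ts <- as_timeseries(ts)
  df <- as.data.frame(t(unclass(ts)))
  colnames(df) <- rownames(ts)
  .write_tsv(df, path)
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE,
                                                scientific = NA))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an atlas TSV (columns: region_id, network)
#' @param path file path.
#' @return a [parcel_atlas()].
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (!all(c("region_id", "network") %in% names(df))) {
    stop("atlas file must have columns region_id, network: ", path, call. = FALSE)
  }
  atlas <- parcel_atlas(df$region_id, df$network)
  missing_nets <- setdiff(CANONICAL_NETWORKS, unique(atlas$network))
  if (length(missing_nets)) {
    warning("atlas uses only ", length(unique(atlas$network)),
            " of the 7 canonical networks (absent: ",
            paste(missing_nets, collapse = ", "), ")", call. = FALSE)
  }
  atlas
}

#' Write an atlas TSV
#' @param atlas a [parcel_atlas()].
#' @param path output path.
#' @export
write_atlas <- function(atlas, path) {
  .write_tsv(as.data.frame(atlas), path)
}

#' Read a cohort manifest and its atlas
#'
#' The manifest is a TSV with columns `subject_id`, `group`, `path` (paths
#' relative to the manifest's directory unless absolute). Every subject file
#' is loaded and its region ids checked against the atlas, in order.
#'
#' @param manifest_path manifest TSV.
#' @param atlas_path atlas TSV.
#' @return list: `subjects` (named list of [timeseries_matrix()]), `manifest`
#'   (data.frame), `atlas`.
#' @export
read_manifest_and_atlas <- function(manifest_path, atlas_path) {
  if (!file.exists(manifest_path)) stop("file not found: ", manifest_path, call. = FALSE)
  man <- utils::read.delim(manifest_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (!all(c("subject_id", "group", "path") %in% names(man))) {
    stop("manifest must have columns subject_id, group, path", call. = FALSE)
  }
  if (anyDuplicated(man$subject_id)) stop("duplicate subject ids in manifest", call. = FALSE)
  atlas <- read_atlas(atlas_path)
  root <- dirname(manifest_path)
  subjects <- list()
  for (i in seq_len(nrow(man))) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(root, man$path[i])
    if (!file.exists(p)) {
      stop(sprintf("subject %s: file not found: %s", man$subject_id[i], man$path[i]),
           call. = FALSE)
    }
    ts <- read_timeseries(p)
    if (!identical(rownames(ts), atlas$region_id)) {
      stop(sprintf("subject %s: region ids do not match the atlas", man$subject_id[i]),
           call. = FALSE)
    }
    subjects[[man$subject_id[i]]] <- ts
  }
  list(subjects = subjects, manifest = man[, c("subject_id", "group")], atlas = atlas)
}

#' Write a simulated cohort to disk
#'
#' One time-series TSV per subject plus `manifest.tsv` (subject_id, group,
#' path) and `atlas.tsv` (region_id, network).
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param atlas optional [parcel_atlas()]; default
#'   `make_default_atlas(n_regions, 7)`.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, atlas = NULL) {
  if (!inherits(cohort, "brainrev_cohort")) stop("not a cohort", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(atlas)) atlas <- make_default_atlas(cohort$spec$n_regions, 7L)
  man <- cohort$manifest
  man$path <- paste0(man$subject_id, ".tsv")
  for (i in seq_len(nrow(man))) {
    write_timeseries(cohort$subjects[[man$subject_id[i]]],
                     file.path(dir, man$path[i]))
  }
  write_atlas(atlas, file.path(dir, "atlas.tsv"))
  .write_tsv(man, file.path(dir, "manifest.tsv"))
  invisible(file.path(dir, "manifest.tsv"))
}

#' Tabulate subject profiles
#'
#' @param profiles list of [subject_profile()] results.
#' @param groups optional named vector mapping subject_id to group label.
#' @return data.frame: `subject_id`, `group`, `n_windows`,
#'   `average_reversibility`, `deviation_reversibility`.
#' @export
profiles_table <- function(profiles, groups = NULL) {
  rows <- lapply(profiles, function(p) {
    data.frame(subject_id = p$subject_id,
               group = if (is.null(groups)) NA_character_ else
                 unname(groups[p$subject_id]),
               n_windows = p$n_windows,
               average_reversibility = p$average_reversibility,
               deviation_reversibility = p$deviation_reversibility,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Long table of per-window values
#' @param profiles list of [subject_profile()] results.
#' @return data.frame: `subject_id`, `window_index`, `I`.
#' @export
windows_table <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    data.frame(subject_id = p$subject_id,
               window_index = seq_along(p$values) - 1L,
               I = p$values, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Long table of network profiles
#' @param net_profiles list of [network_profile()] results.
#' @param groups optional named vector mapping subject_id to group label.
#' @return data.frame: `subject_id`, `group`, `net_a`, `net_b`, `average`,
#'   `deviation`.
#' @export
network_profiles_table <- function(net_profiles, groups = NULL) {
  rows <- lapply(net_profiles, function(p) {
    data.frame(subject_id = p$subject_id,
               group = if (is.null(groups)) NA_character_ else
                 unname(groups[p$subject_id]),
               p$pairs[, c("net_a", "net_b", "average", "deviation")],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
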