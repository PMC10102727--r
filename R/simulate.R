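# Evaluate expr under a local RNG state seeded with `seed`; the caller's
# .Random.seed is untouched, so generators are pure functions of their
# arguments.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

spectral_radius <- function(m) {
  max(Mod(eigen(m, only.values = TRUE)$values))
}

#' Coupling graph from an explicit weight matrix
#'
#' Validates a square lag-1 coupling matrix (zero diagonal, spectral
#' radius < 1) and wraps it for [simulate_var_subject()]. Use
#' [asymmetric_coupling()] to draw one with a controlled asymmetry.
#'
#' @param weights square numeric matrix of directed lag-1 coefficients.
#' @param asymmetry the kappa the weights embody, in `[0, 1]` (metadata).
#' @return a `brainrev_coupling` list: `weights`, `n_regions`, `asymmetry`,
#'   `strength` (the spectral radius).
#' @export
coupling_graph <- function(weights, asymmetry = NA_real_) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights)) {
    stop("weights must be a square matrix", call. = FALSE)
  }
  if (any(diag(weights) != 0)) stop("weights must have a zero diagonal", call. = FALSE)
  rho <- if (nrow(weights) == 1L) 0 else spectral_radius(weights)
  if (rho >= 1) {
    stop("coupling is non-stationary (spectral radius ", signif(rho, 4), " >= 1)",
         call. = FALSE)
  }
  structure(list(weights = weights, n_regions = nrow(weights),
                 asymmetry = asymmetry, strength = rho),
            class = "brainrev_coupling")
}

#' Directed lag-1 coupling graph with controllable asymmetry
#'
#' Draws an `n x n` matrix `D` of independent standard-normal weights (zero
#' diagonal), blends it with its symmetrization as
#' `M = (1 - asymmetry) * (D + t(D))/2 + asymmetry * D`, and rescales `M` so
#' its spectral radius equals `strength`. `asymmetry = 0` (kappa = 0) gives
#' an exactly symmetric coupling — a lag-1 Gaussian process in detailed
#' balance, hence time-reversible; `asymmetry = 1` gives fully independent
#' directed weights, the maximally irreversible regime.
#'
#' @param n_regions positive integer.
#' @param strength spectral radius of the returned weights; must be `< 1` for
#'   a stationary VAR.
#' @param asymmetry kappa in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return a `brainrev_coupling` list: `weights`, `n_regions`, `asymmetry`,
#'   `strength`.
#' @export
asymmetric_coupling <- function(n_regions, strength, asymmetry, seed) {
  n_regions <- as.integer(n_regions)
  if (n_regions < 1L) stop("n_regions must be positive", call. = FALSE)
  if (strength < 0) stop("strength must be nonnegative", call. = FALSE)
  if (strength >= 1) {
    stop("strength must be < 1 for a stationary process, got ", strength,
         call. = FALSE)
  }
  if (asymmetry < 0 || asymmetry > 1) stop("asymmetry must be in [0, 1]", call. = FALSE)
  W <- with_seed(seed, {
    D <- matrix(stats::rnorm(n_regions^2), n_regions, n_regions)
    diag(D) <- 0
    M <- (1 - asymmetry) * (D + t(D)) / 2 + asymmetry * D
    if (n_regions == 1L || strength == 0) {
      M * 0
    } else {
      strength * M / spectral_radius(M)
    }
  })
  structure(list(weights = W, n_regions = n_regions,
                 asymmetry = asymmetry,
                 strength = if (n_regions == 1L) 0 else strength),
            class = "brainrev_coupling")
}

#' Simulate one subject from a lag-1 VAR
#'
#' Generates `x(t) = g(t) * W %*% x(t - 1) + eps(t)` with i.i.d. Gaussian
#' innovations of standard deviation `noise_sd`, discarding a burn-in of
#' `10 * n_regions` samples. With `nonstationarity > 0` the coupling is
#' modulated by a slow multiplicative envelope
#' `g(t) = 1 + nonstationarity * sin(2 * pi * t / length)` completing one full
#' period over the output span, which makes the window-to-window asymmetry
#' fluctuate; stationarity at the envelope peak requires
#' `strength * (1 + nonstationarity) < 1`.
#'
#' @param coupling a [asymmetric_coupling()] result.
#' @param length output length in timepoints, `>= 2`.
#' @param noise_sd innovation standard deviation, `> 0`.
#' @param seed integer RNG seed (same arguments + same seed give bit-identical
#'   output).
#' @param nonstationarity relative envelope amplitude in `[0, 1]`.
#' @return a [timeseries_matrix()], `n_regions x length`.
#' @export
simulate_var_subject <- function(coupling, length, noise_sd = 1, seed = 1L,
                                 nonstationarity = 0) {
  if (!inherits(coupling, "brainrev_coupling")) {
    stop("coupling must come from asymmetric_coupling()", call. = FALSE)
  }
  length <- as.integer(length)
  if (length < 2L) stop("length must be >= 2", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (nonstationarity < 0 || nonstationarity > 1) {
    stop("nonstationarity must be in [0, 1]", call. = FALSE)
  }
  # constructors guarantee strength == spectral radius, so no eigen here
  rho <- coupling$strength
  if (rho >= 1) stop("coupling is non-stationary (spectral radius >= 1)", call. = FALSE)
  if (rho * (1 + nonstationarity) >= 1) {
    stop(sprintf(paste("envelope peak is non-stationary:",
                       "strength * (1 + nonstationarity) = %.3f >= 1"),
                 rho * (1 + nonstationarity)), call. = FALSE)
  }
  n <- coupling$n_regions
  burn <- 10L * n
  total <- burn + length
  W <- coupling$weights
  # envelope indexed relative to the start of the retained span
  g <- 1 + nonstationarity * sin(2 * pi * (seq_len(total) - burn) / length)
  X <- with_seed(seed, {
    eps <- matrix(stats::rnorm(n * total, sd = noise_sd), n, total)
    out <- matrix(0, n, total)
    out[, 1L] <- eps[, 1L]
    for (t in 2L:total) {
      out[, t] <- g[t] * (W %*% out[, t - 1L]) + eps[, t]
    }
    out
  })
  timeseries_matrix(X[, (burn + 1L):total, drop = FALSE])
}

#' Cohort specification
#'
#' Describes a multi-group synthetic cohort. The default emulates the
#' disorders-of-consciousness study design: healthy controls (CNT, n = 13,
#' 195 timepoints), minimally conscious state (MCS, n = 31, 175 timepoints)
#' and unresponsive wakefulness syndrome (UWS, n = 24, 175 timepoints), with
#' coupling asymmetry kappa and envelope nonstationarity both graded
#' CNT > MCS > UWS so that average and deviation reversibility decrease with
#' the level of consciousness.
#'
#' @param groups data.frame with columns `label`, `n_subjects`,
#'   `series_length`, `kappa`, `coupling_scale`, `noise_sd`,
#'   `nonstationarity` (one row per group; labels unique, kappa
#'   non-increasing downward when emulating the study).
#' @param n_regions number of parcels (default 100).
#' @param base_seed integer seed from which all per-subject seeds are derived.
#' @return a `brainrev_cohort_spec` list.
#' @export
cohort_spec <- function(groups, n_regions = 100L, base_seed = 1L) {
  need <- c("label", "n_subjects", "series_length", "kappa",
            "coupling_scale", "noise_sd", "nonstationarity")
  if (!is.data.frame(groups) || !all(need %in% names(groups))) {
    stop("groups must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(groups$label)) stop("duplicate group labels", call. = FALSE)
  if (any(groups$n_subjects < 1L)) stop("all n_subjects must be >= 1", call. = FALSE)
  if (any(groups$series_length < 2L)) stop("series_length must be >= 2", call. = FALSE)
  if (any(groups$kappa < 0 | groups$kappa > 1)) stop("kappa must be in [0, 1]", call. = FALSE)
  structure(list(groups = groups, n_regions = as.integer(n_regions),
                 base_seed = as.integer(base_seed)),
            class = "brainrev_cohort_spec")
}

#' @rdname cohort_spec
#' @param base_seed integer seed.
#' @param n_regions number of parcels.
#' @export
default_cohort_spec <- function(base_seed = 1L, n_regions = 100L) {
  cohort_spec(
    data.frame(label = c("CNT", "MCS", "UWS"),
               n_subjects = c(13L, 31L, 24L),
               series_length = c(195L, 175L, 175L),
               kappa = c(0.8, 0.4, 0.1),
               coupling_scale = 0.5,
               noise_sd = 1,
               nonstationarity = c(0.6, 0.3, 0.15),
               stringsAsFactors = FALSE),
    n_regions = n_regions, base_seed = base_seed
  )
}

#' Stable per-subject seed
#'
#' Polynomial hash of the base seed, the UTF-8 bytes of the group label and
#' the subject index, modulo 2^31 - 1: reproducible independent of iteration
#' order or platform.
#'
#' @param base_seed integer.
#' @param label group label string.
#' @param index 1-based subject index within the group.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
subject_seed <- function(base_seed, label, index) {
  m <- 2147483647
  h <- as.numeric(base_seed) %% m
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% m
  h <- (h * 31 + as.numeric(index)) %% m
  as.integer(h)
}

#' Simulate a full cohort
#'
#' Generates every subject of a [cohort_spec()]: each subject gets its own
#' coupling graph and innovation stream, seeded deterministically via
#' [subject_seed()], so two cohorts built from the same spec are identical.
#'
#' @param spec a [cohort_spec()].
#' @return a `brainrev_cohort` list: `subjects` (named list of
#'   [timeseries_matrix()]), `manifest` (data.frame `subject_id`, `group`),
#'   `spec`.
#' @export
simulate_cohort <- function(spec) {
  if (!inherits(spec, "brainrev_cohort_spec")) {
    stop("spec must come from cohort_spec()", call. = FALSE)
  }
  subjects <- list()
  manifest <- list()
  for (gi in seq_len(nrow(spec$groups))) {
    g <- spec$groups[gi, ]
    for (si in seq_len(g$n_subjects)) {
      sid <- sprintf("%s_%02d", g$label, si)
      seed <- subject_seed(spec$base_seed, g$label, si)
      coup <- asymmetric_coupling(spec$n_regions, g$coupling_scale, g$kappa,
                                  seed = seed)
      noise_seed <- as.integer((as.numeric(seed) + 1) %% 2147483647)
      subjects[[sid]] <- simulate_var_subject(coup, g$series_length,
                                              noise_sd = g$noise_sd,
                                              seed = noise_seed,
                                              nonstationarity = g$nonstationarity)
      manifest[[sid]] <- data.frame(subject_id = sid, group = g$label,
                                    stringsAsFactors = FALSE)
    }
  }
  structure(list(subjects = subjects,
                 manifest = do.call(rbind, c(manifest, make.row.names = FALSE)),
                 spec = spec),
            class = "brainrev_cohort")
}

#' @export
print.brainrev_cohort <- function(x, ...) {
  tab <- table(x$manifest$group)
  cat(sprintf("<cohort> %d subjects (%s), %d regions\n",
              nrow(x$manifest),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              x$spec$n_regions))
  invisible(x)
}
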