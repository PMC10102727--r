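# Shared fixtures and independent oracles.

rand_ts <- function(n, L, seed) {
  set.seed(seed)
  timeseries_matrix(matrix(rnorm(n * L), n))
}

# tiny cohort spec for fast I/O and pipeline tests (window-compatible lengths)
tiny_spec <- function(base_seed = 1L, n_regions = 14L) {
  cohort_spec(
    data.frame(label = c("A", "B", "C"),
               n_subjects = 3L,
               series_length = c(105L, 100L, 100L),
               kappa = c(0.8, 0.4, 0.1),
               coupling_scale = 0.5,
               noise_sd = 1,
               nonstationarity = c(0.6, 0.3, 0.15),
               stringsAsFactors = FALSE),
    n_regions = n_regions, base_seed = base_seed
  )
}

# global irreversibility of an i.i.d. Gaussian (reversible) series
null_global_I <- function(n, L, seed) {
  global_irreversibility(rand_ts(n, L, seed), 1L)
}

# brute-force Benjamini-Hochberg step-up, written independently of bh_adjust
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  q <- numeric(m)
  prev <- 1
  for (k in m:1) {
    prev <- min(prev, ranked[k] * m / k, 1)
    q[k] <- prev
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# exhaustive-enumeration Mann-Whitney oracle (no ties assumed)
enum_ranksum <- function(a, b) {
  m <- length(a)
  n <- length(b)
  rk <- rank(c(a, b))
  u_of <- function(I) sum(rk[I]) - m * (m + 1) / 2
  U_obs <- u_of(seq_len(m))
  Us <- utils::combn(m + n, m, u_of)
  list(U = U_obs,
       p = min(1, 2 * min(mean(Us <= U_obs), mean(Us >= U_obs))))
}

# subject-level summary table straight from a cohort spec (global level only)
cohort_global_table <- function(spec, scheme = windowing_scheme()) {
  cohort <- simulate_cohort(spec)
  groups <- setNames(cohort$manifest$group, cohort$manifest$subject_id)
  profs <- lapply(cohort$manifest$subject_id, function(sid) {
    subject_profile(cohort$subjects[[sid]], scheme, subject_id = sid)
  })
  profiles_table(profs, groups)
}
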