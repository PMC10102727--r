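test_that("time_reverse flips rows, is an involution, fixes palindromes", {
  ts <- timeseries_matrix(matrix(c(1, 2, 3), nrow = 1))
  expect_equal(as.numeric(time_reverse(ts)), c(3, 2, 1))

  ts2 <- rand_ts(4, 50, seed = 1)
  expect_identical(time_reverse(time_reverse(ts2)), ts2)
  expect_identical(rownames(time_reverse(ts2)), rownames(ts2))

  pal <- timeseries_matrix(matrix(c(1, 5, 2, 5, 1), nrow = 1))
  expect_equal(unclass(time_reverse(pal)), unclass(pal), ignore_attr = TRUE)
})

test_that("shifted_pearson: known values, preconditions, degenerate policy", {
  x <- as.numeric(1:10)
  expect_equal(shifted_pearson(x, x, 0), 1.0)
  expect_equal(shifted_pearson(x, -x, 0), -1.0)
  # y(t) = x(t - 1): the shift-1 pairs are (x(t), x(t))
  y <- c(0, x[-10])
  expect_equal(shifted_pearson(x, y, 1), 1.0)

  set.seed(7)
  z <- rnorm(10)
  expect_error(shifted_pearson(z, z, 8), "L - shift")
  const <- rep(1, 10)
  expect_error(shifted_pearson(z, const, 1), "zero-variance")
  expect_warning(r0 <- shifted_pearson(z, const, 1, zero_variance_policy = "zero"),
                 "zero-variance")
  expect_identical(r0, 0)
})

test_that("full_window estimator approaches segment-normalized for long series", {
  set.seed(11)
  x <- rnorm(5000)
  y <- 0.5 * c(0, x[-5000]) + rnorm(5000)
  r_seg <- shifted_pearson(x, y, 1)
  r_full <- shifted_pearson(x, y, 1, estimator = "full_window")
  expect_false(identical(r_seg, r_full))   # edge terms differ
  expect_equal(r_full, r_seg, tolerance = 0.01)
})

test_that("pairwise_irreversibility: self-pairs vanish, reversal-invariant", {
  set.seed(3)
  x <- rnorm(400)
  expect_lt(pairwise_irreversibility(x, x, 1), 1e-12)
  y <- rnorm(400)
  expect_equal(pairwise_irreversibility(x, y, 1),
               pairwise_irreversibility(rev(x), rev(y), 1),
               tolerance = 1e-12)
})

test_that("mutual_info_of_correlation: closed forms, clipping, domain", {
  expect_identical(mutual_info_of_correlation(0), 0)
  expect_equal(mutual_info_of_correlation(1 / sqrt(2)), log(2) / 2)
  expect_equal(mutual_info_of_correlation(1), -0.5 * log(1e-12))
  expect_equal(mutual_info_of_correlation(-0.4), mutual_info_of_correlation(0.4))
  r <- seq(0, 0.99, by = 0.01)
  expect_true(all(diff(mutual_info_of_correlation(r)) > 0))
  expect_error(mutual_info_of_correlation(1.01), "outside")
})

test_that("fs_matrix: scalar consistency, reversal transpose, degenerate naming", {
  ts1 <- rand_ts(1, 60, seed = 5)
  f <- fs_matrix(ts1, 1)
  expect_equal(dim(f), c(1L, 1L))
  expect_equal(f[1, 1],
               mutual_info_of_correlation(shifted_pearson(ts1[1, ], ts1[1, ], 1)))

  # entries match the scalar path elementwise
  ts <- rand_ts(4, 80, seed = 6)
  F <- fs_matrix(ts, 2)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(F[i, j],
                 mutual_info_of_correlation(shifted_pearson(ts[i, ], ts[j, ], 2)),
                 tolerance = 1e-12)
  }

  for (seed in 1:20) {
    ts <- rand_ts(5, 200, seed = seed)
    F <- fs_matrix(ts, 1, "forward")
    R <- fs_matrix(ts, 1, "reversal")
    expect_lt(max(abs(unclass(F) - t(unclass(R)))), 1e-10)
  }

  bad <- timeseries_matrix(rbind(rnorm(30), rep(2, 30)),
                           region_ids = c("ok", "flat"))
  expect_error(fs_matrix(bad, 1), "flat")
})

test_that("reversibility_matrix: shape/shift checks, zero diagonal, arithmetic", {
  ts <- rand_ts(6, 100, seed = 9)
  F <- fs_matrix(ts, 1, "forward")
  R <- fs_matrix(ts, 1, "reversal")
  D <- reversibility_matrix(F, R)
  expect_true(all(D >= 0))
  expect_lt(max(abs(diag(D))), 1e-12)
  expect_lt(max(abs(D - t(D))), 1e-10)   # segment-normalized symmetry

  expect_error(reversibility_matrix(F, fs_matrix(ts, 2, "reversal")), "shift")
  expect_error(reversibility_matrix(F, F), "forward and a reversal")
  R2 <- fs_matrix(rand_ts(3, 100, seed = 1), 1, "reversal")
  expect_error(reversibility_matrix(F, R2), "shape")

  m <- 0.7
  ff <- structure(matrix(c(0, 0, m, 0), 2), shift = 1L, direction = "forward",
                  class = c("brainrev_fs", "matrix", "array"))
  rr <- structure(t(matrix(c(0, 0, m, 0), 2)), shift = 1L, direction = "reversal",
                  class = c("brainrev_fs", "matrix", "array"))
  expect_equal(unclass(reversibility_matrix(ff, rr)),
               matrix(c(0, m^2, m^2, 0), 2), ignore_attr = TRUE)
})

test_that("global_irreversibility invariances: permutation, affine, time-reversal", {
  expect_equal(global_irreversibility(rand_ts(1, 50, seed = 2), 1), 0)

  ts <- rand_ts(6, 120, seed = 13)
  I0 <- global_irreversibility(ts, 1)
  perm <- sample(6)
  expect_equal(global_irreversibility(unclass(ts)[perm, ], 1), I0, tolerance = 1e-12)
  scaled <- unclass(ts) * runif(6, 0.5, 3) + rnorm(6)
  expect_equal(global_irreversibility(scaled, 1), I0, tolerance = 1e-10)
  expect_equal(global_irreversibility(time_reverse(ts), 1), I0, tolerance = 1e-12)

  # excluding the (zero) diagonal rescales the mean by n^2 / (n^2 - n)
  expect_equal(global_irreversibility(ts, 1, exclude_diagonal = TRUE),
               I0 * 36 / 30, tolerance = 1e-10)
})

test_that("null calibration (scaled down): I shrinks with series length", {
  med <- function(L) median(vapply(1:10, function(s) null_global_I(10, L, s),
                                   numeric(1)))
  expect_lt(med(5000), med(300))
})
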