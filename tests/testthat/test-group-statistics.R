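test_that("ranksum_test: exact worked example, ties, swap symmetry", {
  r <- ranksum_test(c(1, 2, 3), c(4, 5, 6))
  expect_identical(r$method, "exact")
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)

  same <- ranksum_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_identical(same$method, "normal")   # ties force the approximation
  expect_gte(same$p, 0.99)

  set.seed(81)
  a <- rnorm(5); b <- rnorm(7)
  r1 <- ranksum_test(a, b); r2 <- ranksum_test(b, a)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_equal(r2$U, length(a) * length(b) - r1$U)

  expect_error(ranksum_test(numeric(0), 1), "nonempty")
})

test_that("exact branch agrees with exhaustive enumeration (n_a, n_b <= 6)", {
  set.seed(82)
  for (m in 2:6) {
    for (n in 2:6) {
      a <- rnorm(m); b <- rnorm(n)
      got <- ranksum_test(a, b)
      want <- enum_ranksum(a, b)
      expect_identical(got$method, "exact")
      expect_equal(got$U, want$U)
      expect_equal(got$p, want$p, tolerance = 1e-12)
    }
  }
})

test_that("normal branch matches the reference tie-corrected approximation", {
  set.seed(83)
  for (i in 1:10) {
    a <- sample(1:8, 12, replace = TRUE)   # plenty of ties
    b <- sample(2:9, 15, replace = TRUE)
    got <- ranksum_test(a, b)
    want <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
    expect_identical(got$method, "normal")
    expect_equal(got$p, unname(want$p.value), tolerance = 1e-12)
  }
})

test_that("bh_adjust: worked example, contract, brute-force agreement", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.5, 0)), "in \\(0, 1\\]")

  set.seed(84)
  for (i in 1:200) {
    p <- runif(sample(1:30, 1))
    q <- bh_adjust(p)
    expect_true(all(q >= p) && all(q <= 1))
    expect_equal(q, bh_brute(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
})

test_that("compare_global: structure, FDR families, input validation", {
  set.seed(85)
  profiles <- data.frame(
    subject_id = sprintf("s%02d", 1:30),
    group = rep(c("CNT", "MCS", "UWS"), each = 10),
    average_reversibility = c(rnorm(10, 6), rnorm(10, 3), rnorm(10, 0)),
    deviation_reversibility = abs(rnorm(30)))
  res <- compare_global(profiles, alpha = 0.05)
  expect_identical(nrow(res), 6L)
  expect_true(all(res$p_fdr >= res$p_raw))
  # family = the 3 pairwise tests of one measure
  avg <- res[res$measure == "average", ]
  expect_equal(avg$p_fdr, bh_adjust(avg$p_raw))
  expect_true(all(avg$significant))

  expect_error(compare_global(profiles[1:10, ]), "at least 2 groups")
  expect_error(compare_global(profiles[c(1, 11:30), ]), ">= 2 subjects")
})

test_that("compare_global null calibration and permutation sanity (scaled down)", {
  null_hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    profiles <- data.frame(
      subject_id = sprintf("s%02d", 1:68),
      group = rep(c("CNT", "MCS", "UWS"), times = c(13, 31, 24)),
      average_reversibility = rnorm(68),
      deviation_reversibility = abs(rnorm(68)))
    res <- compare_global(profiles)
    null_hits <- null_hits + all(res$p_fdr > 0.05)
  }
  # two BH families of 3: P(all clear) ~ 0.95^2 ~ 0.9 per cohort
  expect_gte(null_hits, 15L)

  # a strongly separated cohort loses significance under label permutation
  set.seed(99)
  profiles <- data.frame(
    subject_id = sprintf("s%02d", 1:68),
    group = rep(c("CNT", "MCS", "UWS"), times = c(13, 31, 24)),
    average_reversibility = c(rnorm(13, 5), rnorm(31, 2), rnorm(24, 0)),
    deviation_reversibility = abs(rnorm(68)))
  base <- compare_global(profiles)
  expect_true(all(base$p_fdr[base$measure == "average"] < 0.001))
  perm_p <- vapply(1:20, function(s) {
    set.seed(100 + s)
    shuf <- profiles
    shuf$group <- sample(shuf$group)
    median(compare_global(shuf)$p_fdr[1:3])
  }, numeric(1))
  expect_gt(median(perm_p), 0.2)
})

test_that("compare_networks: 28 cells, two FDR families, triangles", {
  set.seed(86)
  nets <- c("Visual", "Somatomotor", "DorsalAttention", "VentralAttention",
            "Limbic", "Control", "Default")
  key <- expand.grid(b = 1:7, a = 1:7)
  key <- key[key$a >= key$b, ]
  subjects <- sprintf("s%02d", 1:20)
  grp <- rep(c("CNT", "UWS"), each = 10)
  long <- do.call(rbind, lapply(seq_along(subjects), function(i) {
    data.frame(subject_id = subjects[i], group = grp[i],
               net_a = nets[key$a], net_b = nets[key$b],
               average = abs(rnorm(28, ifelse(grp[i] == "CNT", 2, 0.5))),
               deviation = abs(rnorm(28)))
  }))
  out <- compare_networks(long, alpha = 0.05)
  res <- out$results
  expect_identical(nrow(res), 28L * 2L)   # one group pair x 2 measures
  expect_identical(sum(res$net_a == res$net_b), 14L)
  within <- res$measure == "average" & res$net_a == res$net_b
  expect_equal(res$p_fdr_within[within], bh_adjust(res$p_raw[within]))
  all_avg <- res$measure == "average"
  expect_equal(res$p_fdr_all[all_avg], bh_adjust(res$p_raw[all_avg]))

  tri <- out$triangles[["CNT_vs_UWS.average"]]
  expect_identical(sum(!is.na(tri$p_fdr)), 28L)
  expect_true(all(is.na(tri$p_fdr[upper.tri(tri$p_fdr)])))
  expect_true(all(na.omit(as.vector(tri$binarized)) %in% c(0, 1)))
})

test_that("binarize_significance thresholds correctly", {
  tri <- matrix(c(0.005, 0.02, NA, 0.5), 2)
  b <- binarize_significance(tri, 0.01)
  expect_equal(as.vector(b), c(1, 0, NA, 0))
  expect_true(all(binarize_significance(tri, 1)[!is.na(tri)] == 1 |
                    tri[!is.na(tri)] >= 1))
  expect_error(binarize_significance(tri, 0), "alpha")
})
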