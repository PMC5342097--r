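test_that("quantile normalization maps columns to the mean distribution", {
  m <- paired_matrix(matrix(c(1, 2, 3), 3), matrix(c(4, 5, 6), 3),
                     ids = c("a", "b", "c"))[, 1:2, drop = FALSE]
  m2 <- m
  q <- quantile_normalize(m2)
  expect_equal(unname(q[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(q[, 2]), c(2.5, 3.5, 4.5))

  same <- cbind(a = c(1, 5, 9), b = c(1, 5, 9))
  rownames(same) <- c("f1", "f2", "f3")
  expect_equal(quantile_normalize(same), same, ignore_attr = TRUE)

  # ties share the mean of the reference quantiles they span
  tied <- cbind(s1 = c(1, 1, 2), s2 = c(3, 5, 7))
  rownames(tied) <- c("f1", "f2", "f3")
  q2 <- quantile_normalize(tied)
  expect_equal(unname(q2[, "s1"]), c(2.5, 2.5, 4.5))

  one <- matrix(1:3, 3, 1, dimnames = list(letters[1:3], "s1"))
  expect_warning(res <- quantile_normalize(one), ">= 2 samples")
  expect_equal(res, one)
})

test_that("paired differential statistics match the textbook formulas", {
  # per-patient log2 differences of exactly (1, 2, 3, 4)
  tumor <- matrix(2^(1:4) - 1, 1)
  control <- matrix(rep(0, 4), 1)
  m <- paired_matrix(tumor, control, ids = "g1")
  res <- test_differential(m, toy_design(4))
  expect_equal(res$log2_fold_change, 2.5)
  expect_equal(res$t_statistic, 2.5 / (sd(1:4) / 2), tolerance = 1e-10)
  expect_equal(res$t_statistic, 3.872983, tolerance = 1e-6)
  expect_equal(res$p_t_raw, 0.03046629, tolerance = 1e-6)
  expect_equal(res$effect_size, res$t_statistic / 2)

  # identical pairs: no signal, AUC 1/2, flagged zero-variance
  same <- paired_matrix(matrix(c(3, 3, 3), 1), matrix(c(3, 3, 3), 1))
  res0 <- test_differential(same, toy_design(3))
  expect_equal(res0$log2_fold_change, 0)
  expect_equal(res0$auc, 0.5)
  expect_true(res0$zero_variance)
  expect_equal(res0$p_t_raw, 1)
  expect_true(is.na(res0$t_statistic))

  # perfect separation
  sep <- paired_matrix(matrix(c(10, 11, 12), 1), matrix(c(1, 2, 3), 1))
  expect_equal(test_differential(sep, toy_design(3))$auc, 1)

  expect_error(test_differential(same[, c(1, 2, 4, 5), drop = FALSE],
                                 toy_design(3)[c(1, 2, 4, 5), ]),
               "3 matched pairs")
})

test_that("AUC equals the rank-sum statistic over n1*n2 on random data", {
  set.seed(401)
  for (i in 1:50) {
    n <- sample(4:10, 1)
    m <- random_matrix(1, n)
    if (i %% 3 == 0) { # inject ties
      m[1, 1:3] <- m[1, n + (1:3)]
    }
    res <- test_differential(m, toy_design(n))
    tv <- log2(m[1, 1:n] + 1); cv <- log2(m[1, n + 1:n] + 1)
    expect_equal(res$auc, auc_brute(tv, cv))
    u <- unname(wilcox.test(tv, cv, exact = FALSE)$statistic)
    expect_equal(res$auc, u / n^2)
  }
})

test_that("p-value adjustment follows Bonferroni and BH step-up", {
  expect_equal(adjust_pvalues(0.03, "BH"), 0.03)
  expect_equal(adjust_pvalues(c(0.01, rep(0.5, 9)), "bonferroni")[1], 0.1)
  expect_equal(adjust_pvalues(c(0.2, rep(0.5, 9)), "bonferroni")[1], 1)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  expect_identical(adjust_pvalues(numeric(0), "BH"), numeric(0))
  expect_error(adjust_pvalues(c(0.5, 1.2), "BH"), "\\[0, 1\\]")

  set.seed(402)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    bh <- adjust_pvalues(p, "BH")
    bonf <- adjust_pvalues(p, "bonferroni")
    expect_equal(bh, bh_brute(p))
    expect_true(all(bonf >= bh & bh >= p))
  }
})

test_that("direction summaries count significant up/down features", {
  res <- fake_results(paste0("g", 1:20),
                      c(rep("down", 8), rep("up", 12)),
                      c(rep(0.01, 10), rep(0.9, 10)))
  s <- summarize_directions(res, method = "bonferroni")
  expect_equal(s$n_significant, 10)
  expect_equal(s$n_down, 8)
  expect_equal(s$pct_down, 80)

  none <- fake_results("g1", "up", 0.9)
  expect_true(is.na(summarize_directions(none)$pct_down))
})

test_that("PCA scores capture known low-rank structure", {
  # samples on the line y = x in feature space: rank-1 data
  line <- matrix(rep(2^c(1, 2, 3, 5) - 1, each = 2), nrow = 2,
                 byrow = FALSE,
                 dimnames = list(c("f1", "f2"), paste0("s", 1:4)))
  p <- pca_scores(line)
  expect_equal(p$var_explained[1], 1, tolerance = 1e-10)
  expect_equal(sum(p$var_explained), 1, tolerance = 1e-10)

  # two well-separated groups split by sign along a top component
  set.seed(403)
  m <- random_matrix(50, 6)
  m[1:25, 1:6] <- m[1:25, 1:6] * 50
  p2 <- pca_scores(m)
  signs <- sign(p2$scores[, 1])
  expect_true(all(signs[1:6] == signs[1]) &&
                all(signs[7:12] == signs[7]) && signs[1] != signs[7])
  expect_equal(sum(p2$var_explained), 1, tolerance = 1e-10)

  const <- matrix(5, 3, 3, dimnames = list(letters[1:3], letters[4:6]))
  expect_error(pca_scores(const), "constant")
})

test_that("hierarchical clustering merges by average-linkage distance", {
  m <- cbind(s1 = c(1, 2), s2 = c(1, 2), s3 = c(9, 9))
  rownames(m) <- c("f1", "f2")
  hc <- hierarchical_clustering(m)
  expect_equal(hc$tree$height[1], 0) # identical columns merge at 0

  # 1-D points {0, 1, 10} (on the log2(x+1) scale): first merge is {0, 1}
  pts <- matrix(2^c(0, 1, 10) - 1, 1,
                dimnames = list("f", c("a", "b", "c")))
  hc2 <- hierarchical_clustering(pts)
  expect_setequal(abs(hc2$tree$merge[1, ]), c(1, 2))

  # two separated blobs: top split partitions them exactly
  set.seed(404)
  blob <- cbind(matrix(rnorm(20, 5, 0.1), 5), matrix(rnorm(20, 500, 1), 5))
  colnames(blob) <- paste0("s", 1:8)
  rownames(blob) <- paste0("f", 1:5)
  hc3 <- hierarchical_clustering(abs(blob))
  top <- cutree(hc3$tree, 2)
  expect_equal(length(unique(top[paste0("s", 1:4)])), 1)
  expect_equal(length(unique(top[paste0("s", 5:8)])), 1)
  expect_true(top[["s1"]] != top[["s5"]])
})

test_that("t-test and rank-test p-values agree strongly on cohorts", {
  ch <- generate_cohort(sim_config(seed = 7))
  res <- test_differential(quantile_normalize(ch$layers$mRNA), ch$design)
  expect_gte(cor(res$p_t_raw, res$p_wmw_raw, method = "spearman"), 0.7)
})
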