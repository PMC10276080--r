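test_that("Wilcoxon rank-sum gives exact two-sided p-values", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p_value, 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1.0)
  a <- rnorm(6); b <- rnorm(5)
  expect_equal(wilcoxon_rank_sum(a, b),
               wilcoxon_rank_sum(sample(a), sample(b)))
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("BH adjustment implements the step-up procedure", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(2)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p) && all(adj <= 1))
})

test_that("differential usage tests genes across cohorts with BH correction", {
  set.seed(4)
  usage <- cbind(geneA = c(rnorm(4, 30), rnorm(4, 10)),
                 geneB = rnorm(8, 20),
                 geneC = rep(0, 8))
  rownames(usage) <- paste0("s", 1:8)
  labels <- rep(c("g1", "g2"), each = 4)
  du <- differential_usage(usage, labels)
  expect_equal(du$gene, c("geneA", "geneB"))   # all-zero gene excluded
  expect_true(all(du$p_adj >= du$p))
  expect_lt(du$p[du$gene == "geneA"], 0.05)
  expect_error(differential_usage(usage, rep("g1", 8)), "two cohorts")
  expect_error(differential_usage(usage[1:3, ], c("g1", "g1", "g2")),
               "at least 2")
})

test_that("usage PCA is variance-complete, sign-fixed and reconstructable", {
  set.seed(9)
  usage <- matrix(runif(60, 0, 30), nrow = 6,
                  dimnames = list(paste0("s", 1:6), paste0("g", 1:10)))
  pca <- pca_usage(usage)
  expect_equal(sum(pca$percent_var), 100, tolerance = 1e-6)
  for (k in seq_len(ncol(pca$loadings))) {
    v <- pca$loadings[, k]
    expect_gte(v[which.max(abs(v))], 0)
  }
  recon <- pca$scores %*% t(pca$loadings) +
    matrix(pca$center, nrow(usage), ncol(usage), byrow = TRUE)
  expect_equal(unname(recon), unname(log2(usage + 1)), tolerance = 1e-8)

  # rank-1 structure: one component carries all the variance
  base <- runif(8)
  r1 <- 2^(outer(c(1, 2, 3, 4), base)) - 1
  p1 <- pca_usage(r1)
  expect_gt(p1$percent_var[1], 99.999)

  flat <- matrix(5, 4, 3)
  pf <- pca_usage(flat)
  expect_true(all(pf$percent_var == 0))
  expect_true(all(abs(pf$scores) < 1e-12))
})

test_that("pairwise-complete Pearson correlation handles missingness", {
  x <- c(1, 2, 3, 4, NA)
  y <- c(NA, 2, 4, 6, 8)
  res <- pearson_pairwise_complete(cbind(x = x, y = y, z = -x))
  expect_equal(res$r["x", "y"], 1.0)
  expect_equal(res$n["x", "y"], 3)
  expect_equal(res$r["x", "x"], 1)
  expect_equal(res$r["x", "z"], -1)
  expect_true(res$p["x", "z"] < 0.05)
  expect_equal(res$r_masked["x", "z"], -1)

  # a pair with fewer than 3 complete cases is undefined
  u <- c(1, NA, NA, NA, 2)
  res2 <- pearson_pairwise_complete(cbind(x = x, u = u))
  expect_true(is.na(res2$r["x", "u"]))
  # zero variance within complete cases is undefined, not an error
  cnst <- c(3, 3, 3, 3, 3)
  res3 <- pearson_pairwise_complete(cbind(x = x, cnst = cnst))
  expect_true(is.na(res3$r["x", "cnst"]))
})

test_that("group summary comparisons validate cohort coverage", {
  ptab <- data.frame(sample_id = paste0("s", 1:8),
                     cohort = rep(c("a", "b"), each = 4),
                     n_clones = c(5, 6, 7, 8, 5, 6, 7, 8),
                     diversity_q5 = c(1, 2, 3, 4, NA, NA, NA, NA))
  gs <- compare_group_summaries(ptab, "n_clones")
  expect_equal(gs$p, 1)   # identical cohorts
  expect_error(suppressWarnings(
    compare_group_summaries(ptab, "diversity_q5")), "one cohort")
  expect_error(compare_group_summaries(ptab, "nope"), "not found")
})
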