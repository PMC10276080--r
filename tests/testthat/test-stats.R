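test_that("Hill diversity matches closed-form values", {
  expect_equal(hill_diversity(rep(1 / 100, 100), 0), 100)
  expect_equal(hill_diversity(rep(1 / 100, 100), 1), 100)
  expect_equal(hill_diversity(rep(1 / 100, 100), 5), 100)
  expect_equal(hill_diversity(1, 2), 1)
  expect_equal(hill_diversity(c(0.5, 0.25, 0.25), 2), 1 / 0.375)
  expect_error(hill_diversity(c(0.5, 0.5), -1), "q")
  expect_error(hill_diversity(numeric(0), 1), "empty")
  expect_equal(hill_diversity(c(0.5, 0.5, 0), 0), 2)  # zeros ignored
})

test_that("Hill diversity is continuous at q = 1 and non-increasing in q", {
  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(2:40, 1)); p <- p / sum(p)
    d1 <- hill_diversity(p, 1)
    expect_lt(abs(hill_diversity(p, 0.999) - d1) / d1, 1e-3)
    d <- vapply(c(0, 0.5, 1, 2, 5, 10), function(q) hill_diversity(p, q), 0)
    expect_true(all(diff(d) <= 1e-10))
    expect_true(all(d >= 1 - 1e-12 & d <= length(p) + 1e-9))
  }
})

test_that("top-N cumulative frequency sums the largest clones", {
  expect_equal(top_n_cumulative_frequency(rep(0.02, 50), 20), 40)
  expect_equal(top_n_cumulative_frequency(rep(0.2, 5), 20), 100)
  expect_equal(top_n_cumulative_frequency(c(0.4, 0.3, 0.1, 0.1, 0.1), 2), 70)
  # non-decreasing in n, reaches 100 at n = n_clones
  p <- c(0.5, 0.3, 0.15, 0.05)
  vals <- vapply(1:4, function(n) top_n_cumulative_frequency(p, n), 0)
  expect_true(all(diff(vals) >= 0))
  expect_equal(vals[4], 100)
})

test_that("CDR3 length summaries use clone-level medians", {
  s <- cdr3_length_summary(c(14, 15, 16))
  expect_equal(s$median, 15)
  expect_equal(cdr3_length_summary(c(14, 16))$median, 15)
  expect_equal(as.integer(s$hist), c(1L, 1L, 1L))
})

test_that("gene usage collapses alleles and covers the gene universe", {
  calls <- c(rep("IGHV4-34*01", 4), rep("IGHV3-23*04", 3),
             rep("IGHV1-18*01", 3))
  u <- gene_usage(calls, "gene")
  expect_equal(unname(u[["IGHV4-34"]]), 40)
  expect_equal(unname(u[["IGHV3-23"]]), 30)
  expect_equal(sum(u), 100)
  u2 <- gene_usage(calls, "gene", all_genes = c("IGHV5-51*01", calls))
  expect_equal(unname(u2[["IGHV5-51"]]), 0)
  ua <- gene_usage(calls, "allele")
  expect_true("IGHV3-23*04" %in% names(ua))
})

test_that("repertoire profiles summarize a clone table consistently", {
  clones <- data.frame(
    clone_id = 1:5,
    cdr3_aa = c("CARDYW", "CAAAAAW", "CBBBBBW", "CCCCCCW", "CDDDDDW"),
    cdr3_length = c(6L, 7L, 7L, 7L, 7L),
    v_call = c("IGHV4-34*01", "IGHV4-34*01", "IGHV3-23*01", "IGHV1-18*01",
               "IGHV1-18*01"),
    j_call = "IGHJ4*01",
    read_count = c(10L, 5L, 3L, 2L, 2L),
    frequency = c(10, 5, 3, 2, 2) / 22,
    n_members = 1L, stringsAsFactors = FALSE)
  prof <- repertoire_profile(clones, "s1", "A", "IgG", top_n = 2L)
  expect_equal(prof$n_clones, 5L)
  expect_equal(prof$top_n_cumfreq, 100 * 15 / 22)
  expect_equal(prof$median_cdr3_length, 7)
  expect_equal(unname(prof$v_usage[["IGHV4-34"]]), 40)
  expect_equal(unname(prof$diversity["q0"]), 5)
  tab <- profile_table(list(prof))
  expect_equal(tab$n_clones, 5L)
  expect_equal(tab$diversity_q0, 5)
  um <- usage_matrix(list(prof, prof), "V")
  expect_equal(dim(um), c(2L, 3L))
  expect_equal(unname(rowSums(um)), c(100, 100))
})
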