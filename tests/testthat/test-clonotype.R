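test_that("hamming distance counts positional differences only", {
  expect_equal(hamming("CARDYW", "CARDYW"), 0L)
  expect_equal(hamming("CARDYW", "CARDFW"), 1L)
  expect_equal(hamming("CARDGYW", "CAKDFYW"), 2L)
  expect_error(hamming("CARD", "CARDY"), "equal-length")
})

test_that("merge thresholds follow the CDR3-length brackets", {
  expect_equal(merge_threshold(5L), 1L)
  expect_equal(merge_threshold(6L), 1L)
  expect_equal(merge_threshold(7L), 2L)
  expect_equal(merge_threshold(15L), 2L)
  expect_error(merge_threshold(4L), "5 aa")
})

test_that("clones merge by bracketed Hamming distance with single linkage", {
  # distance 1 at length 6 merges; representative is the most abundant
  cl <- cluster_clones(c(rep("CARDYW", 3), rep("CARDFW", 2)))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$read_count, 5L)
  expect_equal(cl$cdr3_aa, "CARDYW")
  expect_equal(cl$n_members, 2L)

  # distance 3 at length 6 stays separate
  cl2 <- cluster_clones(c("CARDYW", "CAKQFW"))
  expect_equal(nrow(cl2), 2L)

  # transitive chain d(A,B)=2, d(B,C)=2, d(A,C)=4 at length 10: one clone
  a <- "AAAAAAAAAA"; b <- "CCAAAAAAAA"; c3 <- "CCCCAAAAAA"
  expect_equal(hamming(a, c3), 4L)
  cl3 <- cluster_clones(c(a, b, c3))
  expect_equal(nrow(cl3), 1L)

  # different lengths never merge
  cl4 <- cluster_clones(c("CARDYW", "CARDYYW"))
  expect_equal(nrow(cl4), 2L)
})

test_that("read-support filtering removes singletons and renormalizes", {
  cl <- cluster_clones(c(rep("CCCCCCCCCC", 3), "AAAAAAAAAA", "GGGGGGGGGG"))
  expect_equal(sort(cl$read_count, decreasing = TRUE), c(3L, 1L, 1L))
  kept <- filter_clones(cl, min_reads = 2L)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$frequency, 1.0)
  expect_equal(nrow(filter_clones(cl, min_reads = 1L)), 3L)  # monotone
  expect_warning(empty <- filter_clones(cl, min_reads = 10L), "removed")
  expect_equal(nrow(empty), 0L)
})

test_that("clustering equals the exhaustive connected-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(12)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:8) {
    n <- sample(30:120, 1)
    lens <- sample(5:12, n, TRUE)
    # small alphabet so that merges actually happen
    cdr3 <- vapply(lens, function(L)
      paste(sample(aa[1:4], L, TRUE), collapse = ""), "")
    counts <- sample(1:4, n, TRUE)
    reads <- rep(cdr3, counts)
    cl <- cluster_clones(reads)
    want <- oracle_components(cdr3)
    # same partition: clones count and identical member groupings
    expect_equal(nrow(cl), length(unique(want)))
    got_groups <- lapply(cl$members, sort)
    want_groups <- lapply(split(cdr3, want), function(x) sort(unique(x)))
    expect_setequal(unname(vapply(got_groups, paste, "", collapse = "|")),
                    unname(vapply(want_groups, paste, "", collapse = "|")))
    # partition property: read counts sum to the number of reads
    expect_equal(sum(cl$read_count), length(reads))
  }
})

test_that("clustering is invariant to input order", {
  set.seed(3)
  aa <- c("A", "C", "D", "E")
  cdr3 <- vapply(1:60, function(i)
    paste(sample(aa, sample(c(6, 8), 1), TRUE), collapse = ""), "")
  cl1 <- cluster_clones(cdr3)
  cl2 <- cluster_clones(rev(cdr3))
  expect_equal(cl1[order(cl1$cdr3_aa), c("cdr3_aa", "read_count", "n_members")],
               cl2[order(cl2$cdr3_aa), c("cdr3_aa", "read_count", "n_members")],
               ignore_attr = TRUE)
})

test_that("same-V restriction splits clones with discordant V calls", {
  cdr3 <- c("CARDYW", "CARDFW")
  same <- cluster_clones(cdr3, v_call = c("IGHV1-1*01", "IGHV1-1*02"),
                         require_same_v = TRUE)
  expect_equal(nrow(same), 1L)   # same gene after allele collapse
  diff <- cluster_clones(cdr3, v_call = c("IGHV1-1*01", "IGHV2-1*01"),
                         require_same_v = TRUE)
  expect_equal(nrow(diff), 2L)
})
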