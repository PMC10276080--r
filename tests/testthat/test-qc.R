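test_that("expected errors follow the Phred formula", {
  expect_equal(expected_errors(rep(20, 100)), 1.0)
  expect_equal(expected_errors(30), 0.001)
  expect_equal(expected_errors(c(10, 20, 30)), 0.111)
  expect_equal(expected_errors(integer(0)), 0)
  expect_error(expected_errors(c(10, -1)), "negative")
})

test_that("expected-error filter keeps E = 2 and drops E > 2", {
  reads <- make_reads(
    seqs = c(strrep("A", 200), strrep("A", 201), strrep("A", 10)),
    quals = c(qual_string(rep(20L, 200)),   # E = 2.00 exactly
              qual_string(rep(20L, 201)),   # E = 2.01
              qual_string(rep(40L, 10))))
  fl <- filter_by_expected_errors(reads, max_ee = 2)
  expect_equal(fl$reads$id, reads$id[c(1, 3)])
  expect_equal(fl$report, list(n_input = 3L, n_kept = 2L, n_discarded = 1L))
  empty <- filter_by_expected_errors(reads[0, ], max_ee = 2)
  expect_equal(nrow(empty$reads), 0L)
  expect_equal(empty$report$n_input, 0L)
})

test_that("kept reads always satisfy the expected-error bound", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    lens <- sample(50:200, n, TRUE)
    reads <- make_reads(
      seqs = vapply(lens, function(L) strrep("A", L), ""),
      quals = vapply(lens, function(L) qual_string(sample(2:41, L, TRUE)), ""))
    fl <- filter_by_expected_errors(reads, max_ee = 2)
    ee <- vapply(fl$reads$qual, function(q)
      expected_errors(utf8ToInt(q) - 33L), 0)
    expect_true(all(ee <= 2))
    expect_true(all(fl$reads$id %in% reads$id))
  }
})

test_that("subsampling is capped, deterministic, and order-independent", {
  small <- make_reads(rep(strrep("A", 10), 10))
  expect_equal(nrow(subsample_reads(small, cap = 15000L, seed = 1)), 10L)

  big <- make_reads(vapply(1:20000, function(i)
    paste0(strrep("A", 5), sprintf("%05d", i)), ""))
  sub <- subsample_reads(big, cap = 15000L, seed = 7)
  expect_equal(nrow(sub), 15000L)
  expect_equal(anyDuplicated(sub$id), 0L)

  sub2 <- subsample_reads(big, cap = 15000L, seed = 7)
  expect_identical(sub, sub2)
  shuffled <- big[sample.int(nrow(big)), ]
  sub3 <- subsample_reads(shuffled, cap = 15000L, seed = 7)
  expect_setequal(sub3$id, sub$id)
  sub4 <- subsample_reads(big, cap = 15000L, seed = 8)
  expect_false(setequal(sub4$id, sub$id))
})

test_that("FASTQ round-trips and corrupt files name the record", {
  reads <- make_reads(c("ACGTACGT", "GGGTTTAA"))
  f <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  back <- read_fastq(f)
  expect_equal(back, reads)
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT"), f)
  expect_error(read_fastq(f), "record 2")
})

test_that("naive pair merging prefers the higher-quality base", {
  fwd <- make_reads("ACGTACGTACGTACGTACGTTT",
                    quals = qual_string(c(rep(40L, 20), rep(10L, 2))))
  # reverse read spanning the same 22 nt, disagreeing at the low-quality tail
  rev_seq <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet("ACGTACGTACGTACGTACGTGG")))
  rev <- make_reads(rev_seq, quals = qual_string(rep(35L, 22)))
  merged <- merge_read_pairs(fwd, rev, min_overlap = 20L)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$seq, "ACGTACGTACGTACGTACGTGG")
})
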