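test_that("local alignment agrees with the reference implementation", {
  # Biostrings::pairwiseAlignment as independent oracle, random pairs
  set.seed(17)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  for (i in 1:40) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(40:250, 1), TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(40:250, 1), TRUE),
               collapse = "")
    d <- align_local(a, b)
    pa <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = 4, gapExtension = 1)
    expect_equal(d$score, Biostrings::score(pa))
    expect_equal(ighrep:::cpp_sw_score_batch(a, b, 1L, -1L, 4L, 1L),
                 Biostrings::score(pa))
  }
})

test_that("reads are assigned to the correct germline with exact identity", {
  v <- fx_v()
  # read identical to a reference
  asg <- assign_segment(v[[2]]$seq, v)
  expect_equal(asg$call, v[[2]]$name)
  expect_equal(asg$identity_nt, 100)
  expect_equal(asg$identity_aa, 100)
  expect_lt(asg$evalue, 1e-3)

  # near-identical pair: read equal to gene A differing from gene B at 12 nt
  a_seq <- strrep("GCTAGA", 52)            # 312 nt, stop-free in frame
  b_seq <- a_seq
  for (p in seq(10, 120, by = 10)) {
    ch <- substr(b_seq, p, p)
    substr(b_seq, p, p) <- setdiff(c("A", "C", "G", "T"), ch)[1]
  }
  pair <- list(germline_gene("IGHVA-1*01", "V", a_seq),
               germline_gene("IGHVB-1*01", "V", b_seq))
  names(pair) <- c("IGHVA-1*01", "IGHVB-1*01")
  expect_equal(assign_segment(a_seq, pair)$call, "IGHVA-1*01")
  expect_equal(assign_segment(b_seq, pair)$call, "IGHVB-1*01")

  # 3 substitutions in a 300-column alignment -> 99.0% identity
  read <- substr(a_seq, 1, 300)
  for (p in c(50, 150, 250)) {
    b <- substr(read, p, p)
    substr(read, p, p) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  asg3 <- assign_segment(read, pair)
  expect_equal(asg3$call, "IGHVA-1*01")
  expect_equal(asg3$identity_nt, 99.0)
})

test_that("mutation profiles tally per region and respect the primer mask", {
  g <- fx_v()[[1]]
  read <- g$seq
  prof0 <- mutation_profile(align_local(read, g$seq), read, g)
  expect_equal(prof0$nt$mismatches, rep(0L, 5))
  expect_equal(sum(prof0$nt$aligned) + prof0$masked_nt, nchar(g$seq))

  # substitution inside the 21-nt primer mask is counted nowhere
  read10 <- read
  substr(read10, 11, 11) <- setdiff(c("A", "C", "G", "T"),
                                    substr(read10, 11, 11))[1]
  prof10 <- mutation_profile(align_local(read10, g$seq), read10, g)
  expect_equal(sum(prof10$nt$mismatches), 0L)
  expect_equal(sum(prof10$aa$mismatches), 0L)

  # two substitutions in one FR3 codon: 2 nt mismatches, 1 aa mismatch
  iv <- codon_interval_to_nt(g, "FR3")
  cstart <- iv[1] + 30L                     # codon-aligned (iv[1] %% 3 == 0)
  read2 <- read
  for (p in cstart + c(2L, 3L)) {   # codon bases 2 and 3 (1-based in read)
    b <- substr(read2, p, p)
    substr(read2, p, p) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  prof2 <- mutation_profile(align_local(read2, g$seq), read2, g)
  expect_equal(prof2$nt$mismatches[prof2$nt$region == "FR3"], 2L)
  expect_equal(sum(prof2$nt$mismatches), 2L)
  expect_equal(prof2$aa$mismatches[prof2$aa$region == "FR3"], 1L)
})

test_that("per-position profiles report mutation frequencies by IMGT position", {
  g <- fx_v()[["IGHV4-34*01"]]
  imgt <- ighrep:::imgt_codon_positions(g)
  # plant aa mutations at IMGT 23/24/25 (the FR1 AVY patch) in 1/2/3 of 10 reads
  reads <- rep(g$seq, 10)
  mutate_codon <- function(s, imgt_pos) {
    k <- which(imgt == imgt_pos)            # ungapped codon index
    p <- 3L * (k - 1L) + 1L
    cod <- substr(s, p, p + 2L)
    new <- if (cod == "GGG") "CCC" else "GGG"
    substr(s, p, p + 2L) <- new
    s
  }
  for (i in 1:1) reads[i] <- mutate_codon(reads[i], 23L)
  for (i in 1:2) reads[i] <- mutate_codon(reads[i], 24L)
  for (i in 1:3) reads[i] <- mutate_codon(reads[i], 25L)
  prof <- positional_mutation_profile(reads, g, motif_positions = 23:25)
  pos <- prof$positions
  expect_equal(pos$frequency[pos$imgt_position == 23], 0.1)
  expect_equal(pos$frequency[pos$imgt_position == 24], 0.2)
  expect_equal(pos$frequency[pos$imgt_position == 25], 0.3)
  expect_equal(prof$motif_mean, 0.2)
  expect_true(all(pos$frequency[!pos$imgt_position %in% 23:25] == 0))

  zero <- positional_mutation_profile(character(0), g)
  expect_true(all(zero$positions$n_reads == 0L))
})
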