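test_that("zero-rate clones match their germline V exactly", {
  cfg <- fx_config(shm = 0, n_clones = 30L)
  rep1 <- simulate_repertoire(fx_germlines(), cfg, donor_seed = 2)
  v <- fx_v()
  for (i in seq_len(nrow(rep1$truth))) {
    g <- v[[rep1$truth$v_gene[i]]]
    expect_equal(substr(rep1$truth$sequence[i], 1, v_fr3_end_nt(g)),
                 substr(g$seq, 1, v_fr3_end_nt(g)))
  }
  expect_true(all(rowSums(rep1$truth[, paste0("n_mut_",
    c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "J"))]) == 0))
})

test_that("planted mutation counts follow the binomial expectation", {
  r <- 0.05
  cfg <- sim_cohort_config(
    n_donors = 1L, clones_per_donor = 1000L,
    shm_rate_per_region = c(FR1 = 0, CDR1 = 0, FR2 = 0, CDR2 = 0,
                            FR3 = r, CDR3 = 0, J = 0),
    reads_per_sample = 1000L, seed = 1L)
  rep1 <- simulate_repertoire(fx_germlines(), cfg, donor_seed = 31)
  v <- fx_v()
  fr3_len <- vapply(rep1$truth$v_gene, function(g)
    diff(codon_interval_to_nt(v[[g]], "FR3")), 0L)
  expected <- mean(r * fr3_len)
  got <- mean(rep1$truth$n_mut_FR3)
  expect_lt(abs(got - expected) / expected, 0.1)
  expect_true(all(rep1$truth$n_mut_FR1 == 0))
})

test_that("clone simulation is deterministic given the seed", {
  cfg <- fx_config()
  set.seed(77); c1 <- simulate_clone(fx_germlines(), cfg)
  set.seed(77); c2 <- simulate_clone(fx_germlines(), cfg)
  expect_identical(c1, c2)
  expect_true(startsWith(c1$truth$cdr3_aa, "C"))
  expect_true(endsWith(c1$truth$cdr3_aa, "W"))
  expect_gte(c1$truth$cdr3_length, 5L)
  expect_lte(c1$truth$cdr3_length, 30L)
})

test_that("emitted reads carry quality-calibrated errors and exact counts", {
  cfg <- fx_config(shm = 0, n_clones = 50L, reads = 2000L)
  cfg$quality_sd <- 0
  rep1 <- simulate_repertoire(fx_germlines(), cfg, donor_seed = 4)
  expect_equal(sum(rep1$truth$true_read_count), 2000L)
  set.seed(4)
  rd <- emit_fastq(rep1$truth, cfg, "D")
  expect_equal(nrow(rd), 2000L)
  # Q40 flat: E = 1e-4 * length; essentially all reads pass E <= 2
  ee <- ighrep:::expected_errors_batch(rd$qual)
  expect_equal(ee, 1e-4 * nchar(rd$seq), tolerance = 1e-8)
  expect_gt(mean(ee <= 2), 0.99)
  # ids encode the source clone
  expect_equal(sort(unique(clone_id_of(rd$id))),
               rep1$truth$clone_id[rep1$truth$true_read_count > 0])

  empty <- rep1$truth
  empty$true_read_count <- 0L
  expect_equal(nrow(emit_fastq(empty, cfg, "D")), 0L)
})

test_that("a steep clone-size exponent concentrates the repertoire", {
  cfg <- fx_config(shm = 0, n_clones = 200L, reads = 5000L)
  cfg$clone_size_exponent <- 5
  rep1 <- simulate_repertoire(fx_germlines(), cfg, donor_seed = 6)
  cnt <- sort(rep1$truth$true_read_count, decreasing = TRUE)
  expect_gt(sum(cnt[1:20]) / sum(cnt), 0.999)
})

test_that("study simulation writes one FASTQ and truth table per donor", {
  a <- fx_config(shm = 0.01, n_clones = 20L, reads = 60L, seed = 1L)
  b <- fx_config(shm = 0.03, n_clones = 20L, reads = 60L, seed = 2L)
  a$n_donors <- b$n_donors <- 3L
  a$label <- "ca"; b$label <- "cb"
  out <- withr::local_tempdir()
  d <- file.path(out, "study")
  man <- simulate_study(a, b, outdir = d)
  expect_equal(nrow(man$sample_sheet), 6L)
  expect_length(list.files(d, pattern = "\\.fastq$"), 6L)
  expect_length(list.files(d, pattern = "_truth\\.tsv$"), 6L)
  expect_true(file.exists(file.path(d, "sample_sheet.tsv")))
  expect_error(simulate_study(a, b, outdir = d), "exists")

  # byte-identical FASTQ under identical seeds
  d2 <- file.path(out, "study2")
  simulate_study(a, b, outdir = d2)
  for (f in list.files(d, pattern = "\\.fastq$")) {
    expect_identical(unname(tools::md5sum(file.path(d, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("noise-free pipelines recover the truth-merging clone count", {
  cfg <- fx_config(shm = 0, n_clones = 150L, reads = 600L, seed = 9L)
  cfg$error_from_quality <- FALSE
  rep1 <- simulate_repertoire(fx_germlines(), cfg, donor_seed = 9)
  set.seed(9)
  rd <- emit_fastq(rep1$truth, cfg, "D")
  res <- run_sample(rd, fx_v(), fx_j(), fx_pssms(), pipeline_config(),
                    "D", seed = 1)
  # oracle: merge emitted truth CDR3s, count merged clones with >= 2 reads
  obs <- rep1$truth[rep1$truth$true_read_count > 0, ]
  comp <- oracle_components(obs$cdr3_aa)
  merged_counts <- tapply(obs$true_read_count, comp, sum)
  expect_equal(res$profile$n_clones, sum(merged_counts >= 2))
})
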