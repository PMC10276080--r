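test_that("PSSM columns reward observed residues and respect the formula", {
  # single reference: every column's best residue is that reference's
  p1 <- suppressWarnings(build_junction_pssms(fx_v()[1], fx_j()[1]))
  g <- fx_v()[[1]]
  aa <- ighrep:::translate_nt(substr(g$seq, 1, v_fr3_end_nt(g)))
  anchors <- ighrep:::v_junction_anchors(g)
  for (jn in 1:5) {
    pm <- p1$pssms[[jn]]
    win <- substr(aa, anchors[jn] - pm$left_w + 1,
                  anchors[jn] + ncol(pm$mat) - pm$left_w)
    ch <- strsplit(win, "")[[1]]
    for (k in seq_along(ch)) {
      expect_equal(rownames(pm$mat)[which.max(pm$mat[1:20, k])], ch[k])
    }
    # training window reaches the maximal achievable score
    self <- ighrep:::score_window(pm$mat, win)
    expect_equal(self, sum(apply(pm$mat[1:20, , drop = FALSE], 2, max)))
  }
  # a column where all 20 residues are equally frequent scores uniformly
  mat <- ighrep:::pssm_matrix(c("ACDEFGHIKLMNPQRSTVWY"), 1, rep(1 / 20, 20))
  expect_equal(length(unique(round(mat[1:20, 1], 10))), 2L)  # seen vs unseen
  mat20 <- ighrep:::pssm_matrix(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                1, rep(1 / 20, 20))
  expect_equal(unname(mat20[1:20, 1]), rep(unname(mat20[1, 1]), 20))
})

test_that("regions are located exactly on unmutated reads and fail on noise", {
  cfg <- fx_config(shm = 0, n_clones = 150L)
  rep1 <- simulate_repertoire(fx_germlines(), cfg, donor_seed = 11)
  loc <- locate_regions(rep1$truth$sequence, fx_pssms())
  expect_true(all(loc$located))
  expect_true(all(loc$frame == 0L))
  got <- as.matrix(loc[, paste0("a", 1:6)])
  want <- as.matrix(rep1$truth[, paste0("a", 1:6)])
  dimnames(got) <- dimnames(want) <- NULL
  expect_equal(got, want)

  set.seed(5)
  noise <- vapply(1:100, function(i)
    paste(sample(c("A", "C", "G", "T"), 360, TRUE), collapse = ""), "")
  locn <- locate_regions(noise, fx_pssms())
  expect_gte(mean(!locn$located), 0.99)
})

test_that("a stop codon before the CDR3 end invalidates the frame", {
  cfg <- fx_config(shm = 0, n_clones = 1L)
  rep1 <- simulate_repertoire(fx_germlines(), cfg, donor_seed = 3)
  s <- rep1$truth$sequence[1]
  # plant TAA mid-FR3 (codon 90, inside FR3 for every reference)
  substr(s, 268, 270) <- "TAA"
  loc <- locate_regions(s, fx_pssms())
  expect_false(loc$located[1])
})

test_that("CDR3 extraction matches simulated truth and flags invalid CDR3s", {
  cfg <- fx_config(shm = 0, n_clones = 100L)
  rep1 <- simulate_repertoire(fx_germlines(), cfg, donor_seed = 21)
  loc <- locate_regions(rep1$truth$sequence, fx_pssms())
  cdr3 <- extract_cdr3(rep1$truth$sequence, loc)
  expect_true(all(cdr3$cdr3_valid))
  expect_equal(cdr3$cdr3_aa, rep1$truth$cdr3_aa)
  expect_true(all(startsWith(cdr3$cdr3_aa, "C")))
  expect_true(all(endsWith(cdr3$cdr3_aa, "W")))

  # fabricated region rows: a stop inside the CDR3, and a 4-aa CDR3
  fake <- data.frame(frame = c(0L, 0L), a1 = 1L, a2 = 2L, a3 = 3L, a4 = 4L,
                     a5 = c(1L, 1L), a6 = c(5L, 3L), score = 0,
                     located = TRUE)
  seqs <- c(paste0("TGT", "GCT", "TAA", "GCT", "GCT", "TGG", "GCT"),
            paste0("TGT", "GCT", "GCT", "TGG", "GCT"))
  out <- extract_cdr3(seqs, fake)
  expect_false(out$cdr3_valid[1])   # contains *
  expect_false(out$cdr3_valid[2])   # 4 aa < minimum
})
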