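# Shared fixtures, built once per test run and cached.
.fx <- new.env(parent = emptyenv())

fx_v <- function() {
  if (is.null(.fx$v)) {
    .fx$v <- read_imgt_fasta(synthetic_germline_path("V"), "V")
  }
  .fx$v
}

fx_j <- function() {
  if (is.null(.fx$j)) {
    .fx$j <- read_imgt_fasta(synthetic_germline_path("J"), "J")
  }
  .fx$j
}

fx_germlines <- function() c(fx_v(), fx_j())

fx_pssms <- function() {
  if (is.null(.fx$pssms)) {
    .fx$pssms <- suppressWarnings(build_junction_pssms(fx_v(), fx_j()))
  }
  .fx$pssms
}

# small uniform-rate cohort config for unit tests
fx_config <- function(shm = 0.02, n_clones = 100L, reads = 500L, seed = 1L) {
  sim_cohort_config(
    n_donors = 1L, clones_per_donor = n_clones,
    shm_rate_per_region = c(FR1 = shm, CDR1 = shm, FR2 = shm, CDR2 = shm,
                            FR3 = shm, CDR3 = shm, J = shm),
    reads_per_sample = reads, seed = seed)
}

# quality string for a vector of Phred scores
qual_string <- function(q, offset = 33L) intToUtf8(q + offset)

# reads table from explicit sequences / qualities
make_reads <- function(seqs, quals = NULL, ids = NULL) {
  if (is.null(quals)) quals <- vapply(nchar(seqs), function(n)
    qual_string(rep(40L, n)), "")
  if (is.null(ids)) ids <- sprintf("read%04d", seq_along(seqs))
  data.frame(id = ids, seq = seqs, qual = quals, stringsAsFactors = FALSE)
}

# truth join: clone id encoded in simulated read ids
clone_id_of <- function(ids) as.integer(sub(".*clone=(\\d+)\\|.*", "\\1", ids))

# brute-force single-linkage clustering of CDR3 strings (independent oracle)
oracle_components <- function(cdr3) {
  n <- length(cdr3)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      if (i == k) next
      if (nchar(cdr3[i]) != nchar(cdr3[k])) next
      d <- sum(strsplit(cdr3[i], "")[[1]] != strsplit(cdr3[k], "")[[1]])
      thr <- if (nchar(cdr3[i]) <= 6) 1L else 2L
      if (d <= thr) adj[i, k] <- TRUE
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

# preset two-cohort study processed end to end; returns summary stats
run_study_summary <- function(seed, reads_per_sample = 15000L,
                              clones_a = 2000L, clones_b = 500L,
                              null_study = FALSE) {
  if (null_study) {
    a <- cohort_preset("no_igrt_like", seed = seed)
    b <- cohort_preset("no_igrt_like", seed = seed + 5000L)
    a$clones_per_donor <- b$clones_per_donor <- clones_b
    a$reads_per_sample <- b$reads_per_sample <- reads_per_sample
    a$label <- "null_a"; b$label <- "null_b"
  } else {
    a <- cohort_preset("needs_igrt_like", seed = seed)
    b <- cohort_preset("no_igrt_like", seed = seed + 5000L)
    a$clones_per_donor <- clones_a
    b$clones_per_donor <- clones_b
    a$reads_per_sample <- b$reads_per_sample <- reads_per_sample
  }
  study <- simulate_study(a, b)
  cfg <- pipeline_config()
  profs <- list()
  for (i in seq_len(nrow(study$sample_sheet))) {
    sid <- study$sample_sheet$sample_id[i]
    res <- run_sample(study$reads[[sid]], fx_v(), fx_j(), fx_pssms(), cfg,
                      sid, study$sample_sheet$cohort[i], "IgG",
                      seed = seed + i)
    profs[[sid]] <- res$profile
  }
  ptab <- profile_table(profs)
  um <- usage_matrix(profs, "V")
  list(profiles = ptab, usage = um,
       differential = differential_usage(um),
       groups = compare_group_summaries(
         ptab, c("n_clones", "diversity_q5", "top_n_cumfreq",
                 "v_identity_nt", "mut_freq_FR3")))
}

# cache of preset replicate studies shared between acceptance blocks
fx_replicates <- function(n = 20L) {
  if (is.null(.fx$reps) || length(.fx$reps) < n) {
    .fx$reps <- lapply(seq_len(n), function(i)
      run_study_summary(seed = 1000L * i))
  }
  .fx$reps[seq_len(n)]
}
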