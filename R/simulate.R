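NT <- c("A", "C", "G", "T")

#' Configuration for one simulated cohort
#'
#' @param label Cohort label.
#' @param n_donors Number of donors (samples).
#' @param clones_per_donor True clones simulated per donor.
#' @param clone_size_exponent Power-law exponent alpha: clone read counts
#'   are drawn with `P(clone at rank r) proportional to r^-alpha` (larger
#'   alpha = more oligoclonal).
#' @param v_usage_weights Named non-negative sampling weights per V allele.
#' @param shm_rate_per_region Named per-nucleotide substitution
#'   probabilities for `FR1, CDR1, FR2, CDR2, FR3, CDR3, J`.
#' @param cdr3_length_mean,cdr3_length_sd CDR3 length (aa, anchors
#'   included) drawn from a discretized normal, clamped to \[5, 30\].
#' @param reads_per_sample Reads emitted per donor.
#' @param mean_quality,quality_sd Per-base Phred scores are drawn from a
#'   normal with these parameters, rounded and clamped to \[2, 41\].
#' @param error_from_quality If TRUE each base is flipped to a random other
#'   base with probability `10^(-Q/10)`.
#' @param seed Integer seed; donor `d` uses `seed + 7919 * d`.
#' @return A `sim_cohort_config` list.
#' @export
sim_cohort_config <- function(label = "cohort",
                              n_donors = 8L,
                              clones_per_donor = 1000L,
                              clone_size_exponent = 1,
                              v_usage_weights = NULL,
                              shm_rate_per_region = c(FR1 = 0.02, CDR1 = 0.04,
                                                      FR2 = 0.02, CDR2 = 0.04,
                                                      FR3 = 0.02, CDR3 = 0.04,
                                                      J = 0.02),
                              cdr3_length_mean = 15, cdr3_length_sd = 2,
                              reads_per_sample = 15000L,
                              mean_quality = 40, quality_sd = 3,
                              error_from_quality = TRUE,
                              seed = 1L) {
  cfg <- list(label = label, n_donors = as.integer(n_donors),
              clones_per_donor = as.integer(clones_per_donor),
              clone_size_exponent = clone_size_exponent,
              v_usage_weights = v_usage_weights,
              shm_rate_per_region = shm_rate_per_region,
              cdr3_length_mean = cdr3_length_mean,
              cdr3_length_sd = cdr3_length_sd,
              reads_per_sample = as.integer(reads_per_sample),
              mean_quality = mean_quality, quality_sd = quality_sd,
              error_from_quality = isTRUE(error_from_quality),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_cohort_config")
}

validate_sim_config <- function(cfg) {
  req <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "J")
  if (!all(req %in% names(cfg$shm_rate_per_region))) {
    stop("shm_rate_per_region must name all of: ", paste(req, collapse = ", "))
  }
  r <- unlist(cfg$shm_rate_per_region)
  if (any(r < 0 | r > 1)) stop("SHM rates must be in [0, 1]")
  if (cfg$n_donors < 1L) stop("n_donors must be >= 1")
  if (!is.null(cfg$v_usage_weights)) {
    w <- unlist(cfg$v_usage_weights)
    if (any(w < 0) || sum(w) == 0) {
      stop("v_usage_weights must be non-negative and not all zero")
    }
  }
  invisible(cfg)
}

#' Preset cohort configurations for a two-cohort study
#'
#' `"needs_igrt_like"`: many clones, even clone sizes, low somatic
#' hypermutation, IGHV4-34-biased usage (weight 3 vs 1).
#' `"no_igrt_like"`: fewer clones, oligoclonal, higher hypermutation,
#' unbiased usage. Both emit 15,000 reads per donor at around Q40 from 8
#' donors.
#'
#' @param name Preset name.
#' @param v_names V allele names of the reference in use (defaults to the
#'   bundled synthetic reference).
#' @param seed Seed (cohort B presets should get a different seed).
#' @return A `sim_cohort_config`.
#' @export
cohort_preset <- function(name = c("needs_igrt_like", "no_igrt_like"),
                          v_names = NULL, seed = 1L) {
  name <- match.arg(name)
  if (is.null(v_names)) {
    v_names <- names(read_imgt_fasta(synthetic_germline_path("V"), "V"))
  }
  w <- setNames(rep(1, length(v_names)), v_names)
  if (name == "needs_igrt_like") {
    w[grepl("^IGHV4-34", v_names)] <- 3
    sim_cohort_config(
      label = name, n_donors = 8L, clones_per_donor = 2000L,
      clone_size_exponent = 0.6, v_usage_weights = w,
      shm_rate_per_region = c(FR1 = 0.01, CDR1 = 0.02, FR2 = 0.01,
                              CDR2 = 0.02, FR3 = 0.01, CDR3 = 0.02,
                              J = 0.01),
      seed = seed)
  } else {
    sim_cohort_config(
      label = name, n_donors = 8L, clones_per_donor = 500L,
      clone_size_exponent = 1.2, v_usage_weights = w,
      shm_rate_per_region = c(FR1 = 0.03, CDR1 = 0.05, FR2 = 0.03,
                              CDR2 = 0.05, FR3 = 0.03, CDR3 = 0.05,
                              J = 0.03),
      seed = seed)
  }
}

# codons that do not encode a stop
NONSTOP_CODONS <- local({
  x <- NULL
  function() {
    if (is.null(x)) {
      gc <- codon_table()
      x <<- names(gc)[gc != "*"]
    }
    x
  }
})

#' Simulate one recombined, hypermutated clone
#'
#' Builds `V[FR1..FR3] + junction insert + J`, with the insert drawn as
#' uniform non-stop codons sized to hit a target CDR3 length (drawn from
#' the configured discretized normal, clamped to \[5, 30\] and to what the
#' chosen J gene allows), then applies somatic hypermutation as independent
#' per-site substitutions at region-specific rates. Uses the session RNG.
#'
#' @param germlines A `germline_set` (V and J genes together) or list with
#'   both segments.
#' @param config A `sim_cohort_config`.
#' @return List with `seq` and a `truth` record (genes, CDR3, planted
#'   per-region mutation counts, true junction anchors).
#' @export
simulate_clone <- function(germlines, config) {
  simulate_clone_cached(sim_cache(germlines, config), config)
}

# precompute per-gene data used by every clone draw
sim_cache <- function(germlines, config) {
  seg <- vapply(germlines, `[[`, "", "segment")
  v_genes <- germlines[seg == "V"]
  j_genes <- germlines[seg == "J"]
  stopifnot(length(v_genes) > 0L, length(j_genes) > 0L)
  shm <- config$shm_rate_per_region
  vs <- lapply(v_genes, function(v) {
    fr3_end <- v_fr3_end_nt(v)
    rates <- numeric(fr3_end)
    bounds <- integer(5)
    for (ri in seq_along(V_REGIONS)) {
      iv <- codon_interval_to_nt(v, V_REGIONS[ri])
      rates[(iv[1] + 1L):iv[2]] <- shm[[V_REGIONS[ri]]]
      bounds[ri] <- iv[1]
    }
    list(name = v$name, chars = strsplit(substr(v$seq, 1L, fr3_end), "")[[1]],
         fr3_end = fr3_end, rates = rates, bounds = bounds,
         anchors = c(bounds[-1] %/% 3L, fr3_end %/% 3L))
  })
  js <- lapply(j_genes, function(j) {
    ja <- j_anchor(j)
    stopifnot(ja$frame == 0L)   # bundled J references are in frame 0
    list(name = j$name, chars = strsplit(j$seq, "")[[1]], w = ja$w,
         len = nchar(j$seq))
  })
  w <- if (is.null(config$v_usage_weights)) {
    rep(1, length(vs))
  } else {
    unlist(config$v_usage_weights)[vapply(vs, `[[`, "", "name")]
  }
  # non-stop codons, exploded to characters
  cod <- NONSTOP_CODONS()
  list(vs = vs, js = js, v_weights = w,
       codon_chars = matrix(unlist(strsplit(cod, "")), nrow = 3L))
}

simulate_clone_cached <- function(cache, config) {
  v <- cache$vs[[sample.int(length(cache$vs), 1L, prob = cache$v_weights)]]
  j <- cache$js[[sample.int(length(cache$js), 1L)]]
  min_len <- max(5L, j$w + 2L)
  L <- round(rnorm(1L, config$cdr3_length_mean, config$cdr3_length_sd))
  L <- min(30L, max(min_len, L))
  k <- L - 2L - j$w                      # insert codons
  ins <- if (k > 0L) {
    as.vector(cache$codon_chars[, sample.int(ncol(cache$codon_chars), k,
                                             replace = TRUE)])
  } else character(0)
  fr3_end <- v$fr3_end
  ch <- c(v$chars, ins, j$chars)
  shm <- config$shm_rate_per_region
  rates <- c(v$rates, rep(shm[["CDR3"]], 3L * k),
             rep(shm[["J"]], j$len))
  hit <- which(runif(length(ch)) < rates)
  regions <- c(V_REGIONS, "CDR3", "J")
  n_mut <- setNames(rep(0L, 7L), regions)
  if (length(hit)) {
    bounds <- c(v$bounds, fr3_end, fr3_end + 3L * k)
    tb <- tabulate(findInterval(hit - 1L, bounds), 7L)
    n_mut[] <- tb
    ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(NT, b), 1L), "")
  }
  seq <- paste(ch, collapse = "")
  cdr3_nt <- c(fr3_end - 3L, fr3_end + 3L * k + 3L * (j$w + 1L))
  cdr3_aa <- translate_nt(substr(seq, cdr3_nt[1] + 1L, cdr3_nt[2]))
  anchors <- c(v$anchors, fr3_end %/% 3L + k + j$w)
  list(seq = seq,
       truth = list(v_gene = v$name, j_gene = j$name, cdr3_aa = cdr3_aa,
                    cdr3_length = nchar(cdr3_aa), n_mut = n_mut,
                    anchors = unname(anchors)))
}

#' Simulate a full donor repertoire (truth table)
#'
#' @param germlines `germline_set` with V and J genes.
#' @param config A `sim_cohort_config`.
#' @param donor_seed Seed for this donor.
#' @return List with `truth` (data.frame, one row per clone, including
#'   `true_read_count` summing to `reads_per_sample`) and `clone_seqs`.
#' @export
simulate_repertoire <- function(germlines, config, donor_seed) {
  cache <- sim_cache(germlines, config)
  set.seed(donor_seed)
  clones <- lapply(seq_len(config$clones_per_donor), function(i)
    simulate_clone_cached(cache, config))
  nc <- length(clones)
  wts <- seq_len(nc)^(-config$clone_size_exponent)
  counts <- as.vector(rmultinom(1L, config$reads_per_sample, wts))
  truth <- data.frame(
    clone_id = seq_len(nc),
    v_gene = vapply(clones, function(x) x$truth$v_gene, ""),
    j_gene = vapply(clones, function(x) x$truth$j_gene, ""),
    cdr3_aa = vapply(clones, function(x) x$truth$cdr3_aa, ""),
    cdr3_length = vapply(clones, function(x) x$truth$cdr3_length, 0L),
    true_read_count = counts,
    stringsAsFactors = FALSE
  )
  mut <- t(vapply(clones, function(x) x$truth$n_mut, numeric(7)))
  colnames(mut) <- paste0("n_mut_", colnames(mut))
  truth <- cbind(truth, as.data.frame(mut))
  truth$sequence <- vapply(clones, `[[`, "", "seq")
  anchors <- t(vapply(clones, function(x) x$truth$anchors, numeric(6)))
  colnames(anchors) <- paste0("a", 1:6)
  truth <- cbind(truth, as.data.frame(anchors))
  list(truth = truth)
}

#' Emit sequencing reads for a simulated donor
#'
#' Reads are drawn from the clone truth table (multiplicities from the
#' power-law draw already stored there); per-base Phred scores come from a
#' clamped normal, and, if `error_from_quality`, each base is flipped to a
#' random other base with probability `10^(-Q/10)`. Read ids encode the
#' donor and true clone id for truth joins.
#'
#' @param truth Truth table from [simulate_repertoire()].
#' @param config A `sim_cohort_config`.
#' @param donor Donor/sample id string.
#' @return Reads table (`id`, `seq`, `qual`).
#' @export
emit_fastq <- function(truth, config, donor = "donor") {
  counts <- truth$true_read_count
  total <- sum(counts)
  if (total == 0L) {
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  clone_of_read <- rep.int(truth$clone_id, counts)
  emitted <- cpp_emit_reads(truth$sequence, counts, config$mean_quality,
                            config$quality_sd, config$error_from_quality)
  data.frame(
    id = sprintf("%s|clone=%d|read=%d", donor, clone_of_read,
                 seq_len(total)),
    seq = emitted$seq, qual = emitted$qual, stringsAsFactors = FALSE
  )
}

#' Simulate a two-cohort repertoire study
#'
#' Generates `n_donors` samples per cohort (truth tables and reads) and,
#' when `outdir` is given, writes one FASTQ per sample, per-sample truth
#' TSVs, and a tab-separated sample sheet (`sample_id`, `cohort`,
#' `isotype`, `fastq_path`). With `outdir = NULL` everything is returned
#' in memory. Deterministic given the config seeds.
#'
#' @param config_a,config_b `sim_cohort_config` for the two cohorts.
#' @param outdir Output directory or NULL.
#' @param overwrite Allow writing into an existing directory.
#' @param isotype Isotype label for the sample sheet.
#' @return Manifest list: `sample_sheet`, `truth` (per sample), `reads`
#'   (per sample, in-memory mode), `configs`.
#' @export
simulate_study <- function(config_a, config_b, outdir = NULL,
                           overwrite = FALSE, isotype = "IgG") {
  cohorts <- list(config_a, config_b)
  if (!is.null(outdir)) {
    if (dir.exists(outdir) && !overwrite) {
      stop("output directory exists (use overwrite = TRUE): ", outdir)
    }
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  }
  germlines <- c(read_imgt_fasta(synthetic_germline_path("V"), "V"),
                 read_imgt_fasta(synthetic_germline_path("J"), "J"))
  labels <- vapply(cohorts, `[[`, "", "label")
  if (labels[1] == labels[2]) labels <- paste0(labels, c("_A", "_B"))
  sheet <- list(); truth <- list(); reads <- list()
  for (ci in 1:2) {
    cfg <- cohorts[[ci]]
    for (d in seq_len(cfg$n_donors)) {
      sid <- sprintf("%s_%02d", labels[ci], d)
      rep_d <- simulate_repertoire(germlines, cfg, cfg$seed + 7919L * d)
      rd <- emit_fastq(rep_d$truth, cfg, sid)
      truth[[sid]] <- rep_d$truth
      fq <- NA_character_
      if (!is.null(outdir)) {
        fq <- file.path(outdir, paste0(sid, ".fastq"))
        write_fastq(rd, fq)
        write.table(rep_d$truth, file.path(outdir, paste0(sid, "_truth.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      } else {
        reads[[sid]] <- rd
      }
      sheet[[sid]] <- data.frame(sample_id = sid, cohort = labels[ci],
                                 isotype = isotype, fastq_path = fq,
                                 stringsAsFactors = FALSE)
    }
  }
  sheet <- do.call(rbind, sheet)
  rownames(sheet) <- NULL
  if (!is.null(outdir)) {
    write.table(sheet, file.path(outdir, "sample_sheet.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(sample_sheet = sheet, truth = truth,
       reads = if (is.null(outdir)) reads else NULL,
       configs = list(a = config_a, b = config_b))
}
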