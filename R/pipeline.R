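#' Build a pipeline configuration
#'
#' Bundles every tunable constant of the pipeline with its default:
#' expected-error ceiling 2, subsampling cap 15,000 reads, clone
#' read-support minimum 2, alignment identity floor 0.5 and E-value
#' ceiling 1e-3, top-20 oligoclonality, 21-nt primer mask, significance
#' level 0.05.
#'
#' @param germline_v,germline_j Germline FASTA paths (default: the bundled
#'   synthetic reference).
#' @param sample_sheet Path to a tab-separated sample sheet with columns
#'   `sample_id`, `cohort`, `isotype`, `fastq_path`.
#' @param outdir Output directory.
#' @param qc,annotation,clonotyping,stats,compare Named lists overriding
#'   individual stage parameters.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(germline_v = synthetic_germline_path("V"),
                            germline_j = synthetic_germline_path("J"),
                            sample_sheet = NULL, outdir = NULL,
                            qc = list(), annotation = list(),
                            clonotyping = list(), stats = list(),
                            compare = list()) {
  merge_opts <- function(defaults, user) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) stop("unknown option(s): ", paste(bad, collapse = ", "))
    defaults[names(user)] <- user
    defaults
  }
  cfg <- list(
    paths = list(germline_v = germline_v, germline_j = germline_j,
                 sample_sheet = sample_sheet, outdir = outdir),
    qc = merge_opts(list(max_ee = 2, subsample_cap = 15000L, seed = 1L,
                         phred_offset = 33L, merge_reads = FALSE), qc),
    annotation = merge_opts(list(pssm_window = 5L, pseudocount = 1,
                                 min_score_frac = 0.6, match = 1L,
                                 mismatch = -1L, gap_open = 4L, gap_ext = 1L,
                                 evalue_max = 1e-3, id_min = 0.5,
                                 primer_mask_nt = 21L), annotation),
    clonotyping = merge_opts(list(min_reads = 2L, require_same_v = FALSE),
                             clonotyping),
    stats = merge_opts(list(diversity_q = c(0, 1, 2, 5), top_n = 20L), stats),
    compare = merge_opts(list(alpha = 0.05, identity_unit = "sample_mean"),
                         compare)
  )
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config(
    germline_v = raw$paths$germline_v %||% synthetic_germline_path("V"),
    germline_j = raw$paths$germline_j %||% synthetic_germline_path("J"),
    sample_sheet = raw$paths$sample_sheet, outdir = raw$paths$outdir,
    qc = raw$qc %||% list(), annotation = raw$annotation %||% list(),
    clonotyping = raw$clonotyping %||% list(), stats = raw$stats %||% list(),
    compare = raw$compare %||% list())
  cfg
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_align_params <- function(config) {
  p <- alignment_params()
  a <- config$annotation
  p[c("match", "mismatch", "gap_open", "gap_ext", "evalue_max", "id_min")] <-
    a[c("match", "mismatch", "gap_open", "gap_ext", "evalue_max", "id_min")]
  p
}

#' Run QC, annotation, clonotyping and profiling for one sample
#'
#' In-memory variant of the per-sample pipeline used by [run_pipeline()].
#'
#' @param reads Reads table.
#' @param v_genes,j_genes Germline lists.
#' @param pssms Junction PSSMs.
#' @param config `pipeline_config`.
#' @param sample_id,cohort,isotype Metadata.
#' @param seed Subsampling seed for this sample.
#' @return List with `profile`, `clones`, `airr`, `report`.
#' @export
run_sample <- function(reads, v_genes, j_genes, pssms, config,
                       sample_id, cohort = NA_character_,
                       isotype = NA_character_, seed = 1L) {
  qc <- filter_by_expected_errors(reads, config$qc$max_ee,
                                  config$qc$phred_offset)
  sub <- subsample_reads(qc$reads, config$qc$subsample_cap, seed)
  ann <- annotate_reads(sub, v_genes, j_genes, pssms,
                        config_align_params(config))
  valid <- ann$airr[ann$airr$valid, , drop = FALSE]
  clones <- NULL
  profile <- NULL
  if (nrow(valid)) {
    clones <- cluster_clones(valid$junction_aa, valid$v_call, valid$j_call,
                             config$clonotyping$require_same_v)
    clones <- filter_clones(clones, config$clonotyping$min_reads)
    if (nrow(clones)) {
      profile <- repertoire_profile(
        clones, sample_id, cohort, isotype,
        q = config$stats$diversity_q, top_n = config$stats$top_n,
        airr = ann$airr,
        all_v = vapply(v_genes, `[[`, "", "name"),
        all_j = vapply(j_genes, `[[`, "", "name"))
    }
  }
  report <- c(list(sample_id = sample_id, n_input = qc$report$n_input,
                   n_pass_ee = qc$report$n_kept,
                   n_subsampled = nrow(sub), seed = seed),
              ann$report[c("n_located", "n_cdr3_valid", "n_assigned")],
              list(n_clonotyped = if (is.null(clones)) 0L
                   else sum(clones$read_count),
                   n_clones = if (is.null(clones)) 0L else nrow(clones)))
  list(profile = profile, clones = clones, airr = ann$airr, report = report)
}

#' Run the full repertoire pipeline over a sample sheet
#'
#' Stages per sample: expected-error filter, subsampling, annotation,
#' clonotyping, profiling; then, per isotype, cohort-level analyses
#' (differential V-gene usage with BH correction, PCA of usage,
#' group-summary tests). All result tables are written under
#' `config$paths$outdir` together with a JSON manifest of configuration,
#' seeds and per-stage attrition counts. Samples yielding zero clones are
#' excluded from cohort statistics with a warning.
#'
#' @param config A `pipeline_config` (or path to a YAML one).
#' @return Invisibly, a list with `profiles`, `reports`, and per-isotype
#'   `comparisons`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  paths <- config$paths
  if (is.null(paths$sample_sheet) || is.null(paths$outdir)) {
    stop("config must set paths$sample_sheet and paths$outdir")
  }
  sheet <- read.delim(paths$sample_sheet, stringsAsFactors = FALSE)
  need <- c("sample_id", "cohort", "isotype", "fastq_path")
  if (!all(need %in% names(sheet))) {
    stop("sample sheet ", paths$sample_sheet, " must have columns: ",
         paste(need, collapse = ", "))
  }
  v_genes <- read_imgt_fasta(paths$germline_v, "V",
                             config$annotation$primer_mask_nt)
  j_genes <- read_imgt_fasta(paths$germline_j, "J")
  pssms <- build_junction_pssms(v_genes, j_genes,
                                config$annotation$pssm_window,
                                config$annotation$pseudocount,
                                config$annotation$min_score_frac)
  dir.create(paths$outdir, recursive = TRUE, showWarnings = FALSE)

  profiles <- list(); reports <- list()
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    reads <- read_fastq(sheet$fastq_path[i], config$qc$phred_offset)
    seed <- (config$qc$seed + string_hash(sid)) %% 2147483647L
    res <- run_sample(reads, v_genes, j_genes, pssms, config, sid,
                      sheet$cohort[i], sheet$isotype[i], seed)
    if (!is.null(res$clones)) {
      write_clones(res$clones, file.path(paths$outdir,
                                         paste0(sid, "_clones.tsv")))
    }
    write_airr(res$airr, file.path(paths$outdir, paste0(sid, "_airr.tsv")))
    if (is.null(res$profile)) {
      warning("sample ", sid, " yielded zero clones and is excluded ",
              "from cohort statistics", call. = FALSE)
    } else {
      profiles[[sid]] <- res$profile
    }
    reports[[sid]] <- res$report
  }
  qc_tab <- do.call(rbind, lapply(reports, as.data.frame))
  write.table(qc_tab, file.path(paths$outdir, "qc_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  comparisons <- list()
  if (length(profiles)) {
    ptab <- profile_table(profiles)
    write.table(ptab, file.path(paths$outdir, "profiles.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (iso in unique(ptab$isotype)) {
      sel <- profiles[ptab$isotype == iso]
      stab <- ptab[ptab$isotype == iso, , drop = FALSE]
      if (length(unique(stab$cohort)) != 2L || min(table(stab$cohort)) < 2L) {
        next
      }
      um <- usage_matrix(sel, "V")
      du <- differential_usage(um)
      pca <- pca_usage(um)
      metrics <- intersect(c("n_clones", "diversity_q5", "top_n_cumfreq",
                             "v_identity_nt", "j_identity_nt",
                             paste0("mut_freq_", V_REGIONS)), names(stab))
      gs <- compare_group_summaries(stab, metrics)
      write.table(du, file.path(paths$outdir,
                                paste0("differential_usage_", iso, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(data.frame(sample_id = rownames(pca$scores),
                             pca$scores[, seq_len(min(4, ncol(pca$scores))),
                                        drop = FALSE]),
                  file.path(paths$outdir, paste0("pca_scores_", iso, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(gs, file.path(paths$outdir,
                                paste0("group_comparisons_", iso, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      comparisons[[iso]] <- list(differential_usage = du, pca = pca,
                                 group_summaries = gs, usage = um)
    }
  }
  manifest <- list(package_version = as.character(utils::packageVersion("ighrep")),
                   config = unclass(config),
                   seeds = vapply(reports, function(r) r$seed, 0),
                   attrition = qc_tab)
  jsonlite::write_json(manifest, file.path(paths$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, dataframe = "rows",
                       force = TRUE)
  invisible(list(profiles = profiles, reports = reports,
                 comparisons = comparisons))
}
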