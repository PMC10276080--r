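#' Hill (true) diversity of a clone frequency vector
#'
#' The effective number of equally common clones:
#' `D_q = (sum p_i^q)^(1/(1-q))` for `q != 1` and
#' `D_1 = exp(-sum p_i log p_i)`. Zero-frequency entries are ignored.
#'
#' @param p Frequency vector (non-negative, summing to 1).
#' @param q Diversity order (>= 0).
#' @return Effective richness, between 1 and the number of clones.
#' @export
hill_diversity <- function(p, q) {
  if (length(p) == 0L) stop("empty frequency vector")
  if (q < 0) stop("diversity order q must be >= 0")
  if (any(p < 0)) stop("negative frequencies")
  if (abs(sum(p) - 1) > 1e-6) stop("frequencies must sum to 1")
  p <- p[p > 0]
  if (q == 1) exp(-sum(p * log(p))) else sum(p^q)^(1 / (1 - q))
}

#' Cumulative frequency of the top-N clones
#'
#' @param frequencies Clone frequency vector.
#' @param n Number of top clones (default 20).
#' @return Percent of the repertoire in the `n` most abundant clones
#'   (100 when there are fewer than `n` clones).
#' @export
top_n_cumulative_frequency <- function(frequencies, n = 20L) {
  100 * sum(sort(frequencies, decreasing = TRUE)[seq_len(min(n, length(frequencies)))])
}

#' CDR3 length histogram and median over clones
#'
#' @param lengths Clone-level CDR3 amino-acid lengths.
#' @return List with `hist` (named count vector) and `median`.
#' @export
cdr3_length_summary <- function(lengths) {
  list(hist = table(lengths), median = median(as.numeric(lengths)))
}

#' Gene usage vector over clones
#'
#' Percent of clones per gene, optionally collapsing alleles to the gene
#' level (`"IGHV3-23*04"` contributes to `"IGHV3-23"`). Genes in
#' `all_genes` that are absent from the sample are reported with 0.
#'
#' @param calls Per-clone gene calls.
#' @param level `"gene"` (collapse alleles) or `"allele"`.
#' @param all_genes Optional universe of gene names (collapsed per `level`).
#' @return Named percent vector summing to 100.
#' @export
gene_usage <- function(calls, level = c("gene", "allele"), all_genes = NULL) {
  level <- match.arg(level)
  calls <- calls[!is.na(calls)]
  if (level == "gene") {
    calls <- collapse_allele(calls)
    all_genes <- if (!is.null(all_genes)) unique(collapse_allele(all_genes))
  }
  lv <- sort(unique(c(calls, all_genes)))
  100 * table(factor(calls, levels = lv)) / length(calls)
}

#' Per-sample repertoire profile
#'
#' Summarizes a filtered clone table: clone count, Hill diversity over a
#' panel of orders, top-N cumulative frequency, CDR3-length distribution,
#' mean germline identities, and V/J usage.
#'
#' @param clones Filtered clone table ([filter_clones()]).
#' @param sample_id,cohort,isotype Sample metadata.
#' @param q Diversity orders (default `c(0, 1, 2, 5)`; the headline
#'   "diversity index" defaults to order 5).
#' @param top_n Number of top clones for the oligoclonality summary.
#' @param airr Optional annotation table (adds mean germline identities and
#'   region mutation frequencies over valid reads).
#' @param all_v,all_j Optional gene-name universes for usage vectors.
#' @return A `repertoire_profile` list.
#' @export
repertoire_profile <- function(clones, sample_id, cohort = NA_character_,
                               isotype = NA_character_, q = c(0, 1, 2, 5),
                               top_n = 20L, airr = NULL,
                               all_v = NULL, all_j = NULL) {
  div <- vapply(q, function(qq) hill_diversity(clones$frequency, qq), 0)
  names(div) <- paste0("q", q)
  cdr3 <- cdr3_length_summary(clones$cdr3_length)
  prof <- list(
    sample_id = sample_id, cohort = cohort, isotype = isotype,
    n_clones = nrow(clones),
    diversity = div,
    top_n = top_n,
    top_n_cumfreq = top_n_cumulative_frequency(clones$frequency, top_n),
    cdr3_length_hist = cdr3$hist,
    median_cdr3_length = cdr3$median,
    v_usage = gene_usage(clones$v_call, "gene", all_v),
    j_usage = gene_usage(clones$j_call, "gene", all_j)
  )
  if (!is.null(airr)) {
    ok <- airr$valid
    prof$v_identity_nt <- mean(airr$v_identity[ok], na.rm = TRUE)
    prof$j_identity_nt <- mean(airr$j_identity[ok], na.rm = TRUE)
    prof$v_identity_aa <- mean(airr$v_identity_aa[ok], na.rm = TRUE)
    prof$j_identity_aa <- mean(airr$j_identity_aa[ok], na.rm = TRUE)
    mut <- colSums(airr[ok, paste0("region_mut_nt_", V_REGIONS)], na.rm = TRUE)
    len <- colSums(airr[ok, paste0("region_len_nt_", V_REGIONS)], na.rm = TRUE)
    prof$region_mut_freq <- setNames(as.numeric(mut) / as.numeric(len),
                                     V_REGIONS)
  }
  structure(prof, class = "repertoire_profile")
}

#' @export
print.repertoire_profile <- function(x, ...) {
  cat(sprintf("<repertoire_profile> %s (%s, %s): %d clones, D5 = %.1f, top-%d = %.1f%%\n",
              x$sample_id, x$cohort, x$isotype, x$n_clones,
              x$diversity[["q5"]], x$top_n, x$top_n_cumfreq))
  invisible(x)
}

#' Flatten repertoire profiles into one row per sample
#'
#' @param profiles List of `repertoire_profile` objects.
#' @return Data.frame with scalar summary columns (diversity orders as
#'   `diversity_q*` columns).
#' @export
profile_table <- function(profiles) {
  rows <- lapply(profiles, function(p) {
    row <- data.frame(sample_id = p$sample_id, cohort = p$cohort,
                      isotype = p$isotype, n_clones = p$n_clones,
                      top_n_cumfreq = p$top_n_cumfreq,
                      median_cdr3_length = p$median_cdr3_length,
                      stringsAsFactors = FALSE)
    for (qn in names(p$diversity)) {
      row[[paste0("diversity_", qn)]] <- p$diversity[[qn]]
    }
    for (f in c("v_identity_nt", "j_identity_nt", "v_identity_aa",
                "j_identity_aa")) {
      if (!is.null(p[[f]])) row[[f]] <- p[[f]]
    }
    if (!is.null(p$region_mut_freq)) {
      for (r in names(p$region_mut_freq)) {
        row[[paste0("mut_freq_", r)]] <- p$region_mut_freq[[r]]
      }
    }
    row
  })
  do.call(rbind, rows)
}

#' Sample-by-gene usage matrix from repertoire profiles
#'
#' @param profiles List of `repertoire_profile` objects.
#' @param segment `"V"` or `"J"`.
#' @return Numeric matrix (samples x genes, percent usage; absent genes 0)
#'   with the cohort labels as the `cohort` attribute.
#' @export
usage_matrix <- function(profiles, segment = c("V", "J")) {
  segment <- match.arg(segment)
  field <- if (segment == "V") "v_usage" else "j_usage"
  genes <- sort(unique(unlist(lapply(profiles, function(p)
    names(p[[field]])))))
  m <- t(vapply(profiles, function(p) {
    v <- setNames(rep(0, length(genes)), genes)
    v[names(p[[field]])] <- as.numeric(p[[field]])
    v
  }, numeric(length(genes))))
  rownames(m) <- vapply(profiles, `[[`, "", "sample_id")
  attr(m, "cohort") <- vapply(profiles, `[[`, "", "cohort")
  m
}
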