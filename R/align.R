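# Gumbel statistics for the default local-alignment scheme
# (match +1, mismatch -1, gap open -4, gap extend -1), estimated once by
# fitting E-value theory to the score distribution of 2,000 alignments of
# random nucleotide pairs (see scratch fit; frozen here as constants).
KA_LAMBDA <- 1.087
KA_K <- 0.093

#' Default local-alignment scoring scheme
#'
#' Match +1, mismatch -1, gap open -4, gap extend -1 (a gap of length L
#' costs `open + L * ext`), with candidate filters: minimum identity 50%
#' and maximum E-value 1e-3.
#'
#' `band` restricts V-gene alignment to a diagonal band (half-width in nt)
#' anchored on the main diagonal, which is exact for amplicons that start
#' at the reference 5' end; set 0 for full dynamic programming.
#' `prescreen` orders candidate references by shared 8-mer counts (the
#' word-count heuristic of USEARCH-style tools) and skips references
#' sharing fewer than 60% of the best candidate's words; with fewer than
#' 16 shared words everything is aligned.
#'
#' @param band Diagonal band half-width for V alignments (default 48).
#' @param prescreen Use the 8-mer candidate prescreen (default TRUE).
#' @return Named list of alignment parameters.
#' @export
alignment_params <- function(band = 48L, prescreen = TRUE) {
  list(match = 1L, mismatch = -1L, gap_open = 4L, gap_ext = 1L,
       id_min = 0.5, evalue_max = 1e-3, lambda = KA_LAMBDA, k = KA_K,
       band = as.integer(band), prescreen = isTRUE(prescreen))
}

evalue <- function(score, m, n, params) {
  params$k * m * n * exp(-params$lambda * score)
}

#' Local alignment of one read against one reference
#'
#' Smith-Waterman with affine gaps under the package's scoring scheme.
#' Exposed mainly for inspection and testing; bulk assignment uses
#' [assign_vj()].
#'
#' @param read,ref Nucleotide strings.
#' @param params Scoring parameters ([alignment_params()]).
#' @return List with `score`, `columns`, `matches`, 0-based half-open
#'   `read_start`/`read_end`/`ref_start`/`ref_end`, and per-column
#'   `read_pos`/`ref_pos` (0-based, -1 in gap columns) and `mismatch`.
#' @export
align_local <- function(read, ref, params = alignment_params()) {
  cpp_sw_align(read, ref, params$match, params$mismatch,
               params$gap_open, params$gap_ext)
}

# codon-aware aa comparison over an alignment: returns per-codon data for
# germline codons fully aligned without indels
codon_comparison <- function(aln, read, ref) {
  ok <- aln$ref_pos >= 0L & aln$read_pos >= 0L
  rp <- aln$ref_pos[ok]; qp <- aln$read_pos[ok]
  cod <- rp %/% 3L
  # a codon is comparable if all 3 of its positions are aligned and the
  # read positions are consecutive
  tab <- rowsum(rep(1L, length(cod)), cod)
  full <- as.integer(rownames(tab))[tab[, 1] == 3L]
  if (length(full) == 0L) {
    return(data.frame(codon = integer(), aa_mismatch = logical()))
  }
  idx <- cod %in% full
  rp3 <- matrix(rp[idx][order(rp[idx])], ncol = 3L, byrow = TRUE)
  qp3 <- matrix(qp[idx][order(rp[idx])], ncol = 3L, byrow = TRUE)
  consec <- (qp3[, 2] - qp3[, 1] == 1L) & (qp3[, 3] - qp3[, 2] == 1L)
  codon <- rp3[, 1] %/% 3L
  gc <- codon_table()
  ref_aa <- gc[substring(ref, rp3[, 1] + 1L, rp3[, 1] + 3L)]
  read_aa <- gc[substring(read, qp3[, 1] + 1L, qp3[, 1] + 3L)]
  data.frame(codon = codon[consec],
             aa_mismatch = (ref_aa != read_aa)[consec] |
               is.na(read_aa[consec]))
}

# 64-character genetic-code string indexed by 16*b1 + 4*b2 + b3 (A,C,G,T)
gc64_string <- local({
  x <- NULL
  function() {
    if (is.null(x)) {
      nt <- c("A", "C", "G", "T")
      cods <- character(64)
      for (b1 in 0:3) for (b2 in 0:3) for (b3 in 0:3) {
        cods[16 * b1 + 4 * b2 + b3 + 1] <-
          paste0(nt[b1 + 1], nt[b2 + 1], nt[b3 + 1])
      }
      x <<- paste(codon_table()[cods], collapse = "")
    }
    x
  }
})

# minimum alignment score compatible with the E-value ceiling
min_score_for_evalue <- function(read_len, n_db, params) {
  ceiling(log(params$k * read_len * n_db / params$evalue_max) / params$lambda)
}

# batched assignment core; genes must be sorted by name so that score ties
# break lexicographically
assign_batch <- function(seqs, genes, params, mask_nt = 0L,
                         with_regions = FALSE) {
  ord <- order(vapply(genes, `[[`, "", "name"))
  genes <- genes[ord]
  refs <- vapply(genes, `[[`, "", "seq")
  n_db <- sum(nchar(refs))
  smin <- min_score_for_evalue(nchar(seqs), n_db, params)
  bounds <- if (with_regions) {
    vapply(genes, function(g)
      c(vapply(V_REGIONS, function(r) codon_interval_to_nt(g, r)[1], 0L),
        v_fr3_end_nt(g)), integer(6))
  } else {
    matrix(integer(0), 0, 0)
  }
  # the diagonal band assumes the read starts near the reference 5' end,
  # which holds for V genes; J genes match a read suffix, so no band there
  band <- if (with_regions) params$band %||% 0L else 0L
  res <- cpp_assign_batch(seqs, refs, params$match, params$mismatch,
                          params$gap_open, params$gap_ext, params$id_min,
                          as.numeric(smin), bounds, as.integer(mask_nt),
                          gc64_string(), band,
                          isTRUE(params$prescreen))
  res$genes <- genes
  res
}

#' Assign V and J germline genes to reads by local alignment
#'
#' Every read is aligned against every reference of a segment; candidates
#' with identity >= 50% and E-value <= 1e-3 are ranked by E-value
#' (`E = K * m * n * exp(-lambda * S)`, database size `n` = total germline
#' residues), ties broken by identity then gene name. Identity is reported
#' at the nucleotide level (matches / aligned columns) and, via codon-aware
#' translation of the aligned region, at the amino-acid level.
#'
#' @param seqs Character vector of read sequences.
#' @param genes `germline_gene` list for one segment (all V or all J).
#' @param params Scoring parameters ([alignment_params()]).
#' @return Data.frame with `call`, `evalue`, `identity_nt`, `identity_aa`
#'   (percent), `score` and `winner_index`; `call` is NA for unassigned
#'   reads.
#' @export
assign_segment <- function(seqs, genes, params = alignment_params()) {
  res <- assign_batch(seqs, genes, params)
  n_db <- sum(vapply(res$genes, function(g) nchar(g$seq), 0L))
  won <- res$winner > 0L
  nm <- vapply(res$genes, `[[`, "", "name")
  data.frame(
    call = ifelse(won, nm[pmax(res$winner, 1L)], NA_character_),
    evalue = ifelse(won, evalue(res$score, nchar(seqs), n_db, params),
                    NA_real_),
    identity_nt = ifelse(won, 100 * res$matches / pmax(res$columns, 1L),
                         NA_real_),
    identity_aa = ifelse(won & res$aa_cols > 0,
                         100 * res$aa_matches / pmax(res$aa_cols, 1L),
                         NA_real_),
    score = ifelse(won, res$score, NA_integer_),
    winner_index = ifelse(won, res$winner, NA_integer_),
    stringsAsFactors = FALSE
  )
}

V_REGIONS <- c("FR1", "CDR1", "FR2", "CDR2", "FR3")

#' Per-region mutation profile of a read against its germline V gene
#'
#' Tallies mismatches per framework/CDR region over aligned germline
#' positions, excluding the 5' primer mask (`primer_mask_nt` germline
#' nucleotides; mutations there cannot be measured). Amino-acid tallies use
#' codon-aware translation of fully aligned codons. Regions not covered by
#' the alignment report 0 aligned positions (excluded from frequencies, not
#' treated as unmutated).
#'
#' @param detail Alignment detail from [align_local()].
#' @param read Read sequence.
#' @param gene The assigned `germline_gene` (V).
#' @return List with `nt` and `aa` data.frames (`region`, `mismatches`,
#'   `aligned`, `frequency`) and `masked_nt` (masked aligned positions).
#' @export
mutation_profile <- function(detail, read, gene) {
  stopifnot(gene$segment == "V")
  bounds <- vapply(V_REGIONS, function(r)
    codon_interval_to_nt(gene, r)[1], 0L)
  fr3_end <- v_fr3_end_nt(gene)
  ok <- detail$ref_pos >= 0L & detail$read_pos >= 0L
  rp <- detail$ref_pos[ok]
  mm <- detail$mismatch[ok] == 1L
  masked <- rp < gene$primer_mask_nt
  inV <- rp < fr3_end
  use <- !masked & inV
  reg <- findInterval(rp[use], c(bounds, fr3_end))
  nt <- data.frame(region = V_REGIONS,
                   mismatches = 0L, aligned = 0L)
  if (any(use)) {
    al <- table(factor(reg, levels = 1:5))
    mu <- rowsum(as.integer(mm[use]), factor(reg, levels = 1:5))
    nt$aligned <- as.integer(al)
    nt$mismatches <- as.integer(mu[, 1])
  }
  nt$frequency <- ifelse(nt$aligned > 0, nt$mismatches / nt$aligned, NA_real_)

  cmp <- codon_comparison(detail, read, gene$seq)
  aa <- data.frame(region = V_REGIONS, mismatches = 0L, aligned = 0L)
  if (nrow(cmp)) {
    cod_start <- cmp$codon * 3L
    keep <- cod_start >= gene$primer_mask_nt & cod_start < fr3_end
    if (any(keep)) {
      rega <- findInterval(cod_start[keep], c(bounds, fr3_end))
      al <- table(factor(rega, levels = 1:5))
      mu <- rowsum(as.integer(cmp$aa_mismatch[keep]),
                   factor(rega, levels = 1:5))
      aa$aligned <- as.integer(al)
      aa$mismatches <- as.integer(mu[, 1])
    }
  }
  aa$frequency <- ifelse(aa$aligned > 0, aa$mismatches / aa$aligned, NA_real_)
  list(nt = nt, aa = aa, masked_nt = sum(masked & inV))
}

#' Per-position mutation frequencies along one V gene
#'
#' Re-aligns the reads assigned to `gene` and reports, per IMGT amino-acid
#' position, the fraction of reads mutated there (codon-aware). A motif
#' query (e.g. the FR1 "AVY" hydrophobic-patch positions of IGHV4-34)
#' returns the mean frequency over the requested positions.
#'
#' @param seqs Sequences of reads assigned to `gene`.
#' @param gene A `germline_gene` (V).
#' @param motif_positions Optional integer IMGT aa positions to average.
#' @param params Scoring parameters.
#' @return List with `positions` (data.frame `imgt_position`, `n_reads`,
#'   `n_mutated`, `frequency`) and `motif_mean` (NA if no motif given).
#' @export
positional_mutation_profile <- function(seqs, gene, motif_positions = NULL,
                                        params = alignment_params()) {
  imgt <- imgt_codon_positions(gene)
  n_mut <- n_obs <- setNames(rep(0L, length(imgt)), imgt)
  if (length(seqs)) {
    for (s in seqs) {
      d <- align_local(s, gene$seq, params)
      cmp <- codon_comparison(d, s, gene$seq)
      if (!nrow(cmp)) next
      idx <- cmp$codon + 1L
      ok <- idx >= 1L & idx <= length(imgt)
      n_obs[idx[ok]] <- n_obs[idx[ok]] + 1L
      n_mut[idx[ok]] <- n_mut[idx[ok]] + as.integer(cmp$aa_mismatch[ok])
    }
  }
  pos <- data.frame(imgt_position = imgt, n_reads = as.integer(n_obs),
                    n_mutated = as.integer(n_mut),
                    frequency = ifelse(n_obs > 0, n_mut / n_obs, NA_real_))
  motif_mean <- NA_real_
  if (!is.null(motif_positions)) {
    sel <- pos$frequency[pos$imgt_position %in% motif_positions]
    motif_mean <- mean(sel)
  }
  list(positions = pos, motif_mean = motif_mean)
}
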