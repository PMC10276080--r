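#' Annotate reads: regions, CDR3, V/J calls, germline identity, mutations
#'
#' Runs the full per-read annotation for one sample: dereplicates identical
#' sequences, locates framework/CDR boundaries with junction PSSMs,
#' extracts the CDR3, assigns V and J germline genes by local alignment,
#' and computes germline identities and per-region mutation tallies (with
#' the 5' primer mask excluded). A read is `valid` (and enters
#' clonotyping) when regions were located, the CDR3 is valid, and both V
#' and J were assigned.
#'
#' @param reads Reads table (`id`, `seq`, and optionally `qual`).
#' @param v_genes,j_genes Germline lists from [read_imgt_fasta()].
#' @param pssms Junction PSSMs from [build_junction_pssms()].
#' @param params Alignment parameters ([alignment_params()]).
#' @return List with `airr` (one row per read, AIRR-style columns) and
#'   `report` (attrition counts).
#' @export
annotate_reads <- function(reads, v_genes, j_genes, pssms,
                           params = alignment_params()) {
  n <- nrow(reads)
  uniq <- unique(reads$seq)
  map <- match(reads$seq, uniq)
  nu <- length(uniq)

  regions <- locate_regions(uniq, pssms)
  cdr3 <- extract_cdr3(uniq, regions)
  todo <- which(regions$located & cdr3$cdr3_valid)

  v_call <- j_call <- rep(NA_character_, nu)
  v_idnt <- v_idaa <- j_idnt <- j_idaa <- rep(NA_real_, nu)
  masked <- rep(NA_integer_, nu)
  nreg <- length(V_REGIONS)
  mut_nt <- matrix(NA_integer_, nu, 2L * nreg,
                   dimnames = list(NULL, c(paste0("region_mut_nt_", V_REGIONS),
                                           paste0("region_len_nt_", V_REGIONS))))
  mut_aa <- matrix(NA_integer_, nu, 2L * nreg,
                   dimnames = list(NULL, c(paste0("region_mut_aa_", V_REGIONS),
                                           paste0("region_len_aa_", V_REGIONS))))
  if (length(todo)) {
    mask <- v_genes[[1]]$primer_mask_nt
    vb <- assign_batch(uniq[todo], v_genes, params, mask_nt = mask,
                       with_regions = TRUE)
    jb <- assign_batch(uniq[todo], j_genes, params)
    vnm <- vapply(vb$genes, `[[`, "", "name")
    jnm <- vapply(jb$genes, `[[`, "", "name")
    vw <- vb$winner > 0L
    jw <- jb$winner > 0L
    v_call[todo[vw]] <- vnm[vb$winner[vw]]
    j_call[todo[jw]] <- jnm[jb$winner[jw]]
    v_idnt[todo[vw]] <- 100 * vb$matches[vw] / vb$columns[vw]
    j_idnt[todo[jw]] <- 100 * jb$matches[jw] / jb$columns[jw]
    v_idaa[todo[vw]] <- ifelse(vb$aa_cols[vw] > 0,
                               100 * vb$aa_matches[vw] / vb$aa_cols[vw],
                               NA_real_)
    j_idaa[todo[jw]] <- ifelse(jb$aa_cols[jw] > 0,
                               100 * jb$aa_matches[jw] / jb$aa_cols[jw],
                               NA_real_)
    masked[todo[vw]] <- vb$masked[vw]
    mut_nt[todo[vw], ] <- cbind(vb$nt_mm, vb$nt_al)[vw, , drop = FALSE]
    mut_aa[todo[vw], ] <- cbind(vb$aa_mm, vb$aa_al)[vw, , drop = FALSE]
  }

  valid_u <- regions$located & cdr3$cdr3_valid &
    !is.na(v_call) & !is.na(j_call)

  airr <- data.frame(
    sequence_id = reads$id,
    sequence = reads$seq,
    locus = "IGH",
    v_call = v_call[map],
    j_call = j_call[map],
    junction_aa = ifelse(cdr3$cdr3_valid[map], cdr3$cdr3_aa[map],
                         NA_character_),
    junction_aa_length = ifelse(cdr3$cdr3_valid[map],
                                nchar(cdr3$cdr3_aa[map]), NA_integer_),
    v_identity = v_idnt[map],
    j_identity = j_idnt[map],
    v_identity_aa = v_idaa[map],
    j_identity_aa = j_idaa[map],
    frame = regions$frame[map],
    masked_nt = masked[map],
    stringsAsFactors = FALSE
  )
  airr <- cbind(airr, as.data.frame(mut_nt[map, , drop = FALSE]),
                as.data.frame(mut_aa[map, , drop = FALSE]))
  airr$valid <- valid_u[map]

  report <- list(
    n_reads = n,
    n_unique = nu,
    n_located = sum(regions$located[map]),
    n_cdr3_valid = sum((regions$located & cdr3$cdr3_valid)[map]),
    n_assigned = sum(valid_u[map])
  )
  list(airr = airr, report = report)
}

#' Write an annotation table as AIRR-style rearrangement TSV
#'
#' @param airr Annotation data.frame from [annotate_reads()].
#' @param path Output TSV.
#' @export
write_airr <- function(airr, path) {
  drop <- vapply(airr, is.list, TRUE)
  write.table(airr[, !drop, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
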