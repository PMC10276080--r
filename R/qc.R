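#' Read a FASTQ file into a reads table
#'
#' @param path FASTQ file (Phred+33 by default).
#' @param phred_offset Quality encoding offset.
#' @return A data.frame with columns `id`, `seq`, `qual` (quality string in
#'   the file's encoding; see [expected_errors()]).
#' @export
read_fastq <- function(path, phred_offset = 33L) {
  if (!file.exists(path)) stop("file not found: ", path)
  fail <- function(rec, why) {
    stop("malformed FASTQ in ", path,
         if (!is.na(rec)) paste0(" at record ", rec), ": ", why,
         call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L) {
    fail(length(lines) %/% 4L + 1L, "truncated record")
  }
  out <- tryCatch({
    recs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                         with.qualities = TRUE)
    data.frame(
      id = sub("[ \t].*$", "", names(recs)),
      seq = as.character(recs),
      qual = as.character(S4Vectors::mcols(recs)$qualities),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }, error = function(e) NULL)
  if (is.null(out)) {
    bad <- which(nchar(lines[seq(2L, length(lines), 4L)]) !=
                   nchar(lines[seq(4L, length(lines), 4L)]))
    fail(if (length(bad)) bad[1] else NA_integer_,
         "could not parse sequence/quality records")
  }
  mism <- which(nchar(out$seq) != nchar(out$qual))
  if (length(mism)) fail(mism[1], "sequence and quality lengths differ")
  out
}

#' Write a reads table to FASTQ
#'
#' @param reads Data.frame with `id`, `seq`, `qual`.
#' @param path Output file.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Expected number of sequencing errors from Phred scores
#'
#' `E = sum_i 10^(-Q_i / 10)`, the expectation of the number of erroneous
#' bases in a read given its per-base quality scores.
#'
#' @param quals Integer (or numeric) vector of Phred scores, all >= 0.
#' @return Expected error count (0 for an empty vector).
#' @export
expected_errors <- function(quals) {
  if (length(quals) == 0L) return(0)
  if (any(quals < 0)) stop("negative Phred score")
  sum(10^(-quals / 10))
}

# batch expected errors from quality strings (one value per read)
expected_errors_batch <- function(qual_strings, phred_offset = 33L) {
  if (length(qual_strings) == 0L) return(numeric(0))
  cpp_expected_errors(qual_strings, as.integer(phred_offset))
}

#' Filter reads by expected errors
#'
#' Keeps reads whose expected error count `E` is at most `max_ee` (reads
#' with `E` strictly greater than the threshold are discarded).
#'
#' @param reads Reads table from [read_fastq()].
#' @param max_ee Maximum expected errors (default 2).
#' @param phred_offset Quality encoding offset.
#' @return List with `reads` (kept rows) and `report`
#'   (`n_input`, `n_kept`, `n_discarded`).
#' @export
filter_by_expected_errors <- function(reads, max_ee = 2, phred_offset = 33L) {
  ee <- expected_errors_batch(reads$qual, phred_offset)
  # small absolute slack so that reads summing to the threshold exactly
  # (e.g. 200 bases at Q20 -> E = 2) are kept despite binary rounding
  keep <- ee <= max_ee + 1e-9
  list(reads = reads[keep, , drop = FALSE],
       report = list(n_input = nrow(reads), n_kept = sum(keep),
                     n_discarded = sum(!keep)))
}

#' Randomly subsample reads to a fixed cap
#'
#' Uniform sampling without replacement. Reads are ordered by id before
#' sampling so the sampled multiset depends only on the seed and the id
#' set, not on input order.
#'
#' @param reads Reads table.
#' @param cap Maximum number of reads to keep (default 15000).
#' @param seed Integer seed.
#' @return Reads table with `min(cap, nrow(reads))` rows.
#' @export
subsample_reads <- function(reads, cap = 15000L, seed = 1L) {
  stopifnot(cap >= 0)
  if (nrow(reads) <= cap) return(reads)
  ord <- order(reads$id)
  reads <- reads[ord, , drop = FALSE]
  idx <- with_seed(seed, sample.int(nrow(reads), cap))
  out <- reads[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Naive overlap merger for paired-end reads (optional stage)
#'
#' Merges forward/reverse pairs by scanning overlaps of at least
#' `min_overlap` nt, accepting the longest overlap whose mismatch rate is
#' at most `max_mismatch_rate`; at disagreeing positions the base with the
#' higher quality wins. The reverse read is reverse-complemented first.
#'
#' @param fwd,rev Reads tables of equal length (pairs in order).
#' @param min_overlap Minimum overlap length.
#' @param max_mismatch_rate Maximum fraction of mismatching overlap
#'   positions.
#' @param phred_offset Quality encoding offset.
#' @return Reads table of merged reads (unmergeable pairs dropped).
#' @export
merge_read_pairs <- function(fwd, rev, min_overlap = 20L,
                             max_mismatch_rate = 0.1, phred_offset = 33L) {
  stopifnot(nrow(fwd) == nrow(rev))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rev$seq)))
  rq <- vapply(rev$qual, function(q)
    intToUtf8(rev(utf8ToInt(q))), "", USE.NAMES = FALSE)
  out <- vector("list", nrow(fwd))
  for (i in seq_len(nrow(fwd))) {
    a <- fwd$seq[i]; b <- rc[i]
    qa <- fwd$qual[i]; qb <- rq[i]
    na <- nchar(a); nb <- nchar(b)
    merged <- NULL
    if (min(na, nb) < min_overlap) next
    for (ov in seq(min(na, nb), min_overlap)) {
      sa <- utf8ToInt(substr(a, na - ov + 1L, na))
      sb <- utf8ToInt(substr(b, 1L, ov))
      mm <- sa != sb
      if (mean(mm) <= max_mismatch_rate) {
        qav <- utf8ToInt(substr(qa, na - ov + 1L, na))
        qbv <- utf8ToInt(substr(qb, 1L, ov))
        cons <- ifelse(qav >= qbv, sa, sb)
        consq <- pmax(qav, qbv)
        merged <- list(
          seq = paste0(substr(a, 1L, na - ov), intToUtf8(cons),
                       substr(b, ov + 1L, nb)),
          qual = paste0(substr(qa, 1L, na - ov), intToUtf8(consq),
                        substr(qb, ov + 1L, nb)))
        break
      }
    }
    if (!is.null(merged)) {
      out[[i]] <- data.frame(id = fwd$id[i], seq = merged$seq,
                             qual = merged$qual, stringsAsFactors = FALSE)
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) {
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
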