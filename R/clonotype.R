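#' Hamming distance between equal-length amino-acid strings
#'
#' @param a,b Strings of equal length.
#' @return Integer count of differing positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("hamming distance is defined only for equal-length strings")
  }
  cpp_hamming(a, b)
}

#' CDR3-length-dependent clone merging threshold
#'
#' Unique CDR3s are merged at up to 1 amino-acid difference for 5-6 aa
#' CDR3s and up to 2 differences for CDR3s longer than 6 aa.
#'
#' @param cdr3_length CDR3 length in amino acids (>= 5).
#' @return Maximum number of amino-acid differences that still merges.
#' @export
merge_threshold <- function(cdr3_length) {
  if (any(cdr3_length < 5L)) stop("CDR3 shorter than 5 aa cannot be clonotyped")
  ifelse(cdr3_length <= 6L, 1L, 2L)
}

#' Cluster annotated reads into clones by CDR3 similarity
#'
#' Within each CDR3 length class, unique CDR3 amino-acid strings are nodes
#' and pairs within the length-dependent Hamming threshold
#' ([merge_threshold()]) are edges; clones are the connected components
#' (single linkage). The representative CDR3 is the most abundant member
#' (ties broken lexicographically) and V/J calls are majority votes over
#' member reads.
#'
#' @param junction_aa CDR3 amino-acid string per read.
#' @param v_call,j_call Optional per-read gene calls.
#' @param require_same_v If TRUE, reads only merge within the same
#'   (gene-collapsed) V call.
#' @return Data.frame with one row per clone: `clone_id`, `cdr3_aa`,
#'   `cdr3_length`, `v_call`, `j_call`, `read_count`, `frequency`,
#'   `n_members`, plus a `members` list column of unique member CDR3s.
#' @export
cluster_clones <- function(junction_aa, v_call = NULL, j_call = NULL,
                           require_same_v = FALSE) {
  stopifnot(length(junction_aa) > 0L)
  n <- length(junction_aa)
  v_call <- v_call %||% rep(NA_character_, n)
  j_call <- j_call %||% rep(NA_character_, n)
  len <- nchar(junction_aa)
  merge_threshold(min(len))   # validates the length floor
  block <- if (require_same_v) {
    paste(len, collapse_allele(v_call), sep = "|")
  } else {
    as.character(len)
  }
  clone_of_read <- integer(n)
  next_id <- 0L
  for (b in unique(block)) {
    idx <- which(block == b)
    u <- unique(junction_aa[idx])
    comp <- cpp_hamming_components(u, merge_threshold(nchar(u[1])))
    clone_of_read[idx] <- next_id + comp[match(junction_aa[idx], u)]
    next_id <- next_id + max(comp)
  }
  nclone <- max(clone_of_read)
  read_count <- tabulate(clone_of_read, nclone)
  # representative CDR3: most reads, ties lexicographic
  u_all <- unique(junction_aa)
  u_clone <- clone_of_read[match(u_all, junction_aa)]
  u_count <- tabulate(match(junction_aa, u_all), length(u_all))
  ou <- order(u_clone, -u_count, u_all)
  first <- !duplicated(u_clone[ou])
  rep_cdr3 <- character(nclone)
  rep_cdr3[u_clone[ou][first]] <- u_all[ou][first]
  n_members <- tabulate(u_clone, nclone)
  majority <- function(x) {
    ux <- unique(x[!is.na(x)])
    if (length(ux) == 0L) return(NA_character_)
    if (length(ux) == 1L) return(ux)
    tb <- table(x[!is.na(x)])
    sort(names(tb)[tb == max(tb)])[1]
  }
  vmaj <- vapply(split(v_call, clone_of_read), majority, "")
  jmaj <- vapply(split(j_call, clone_of_read), majority, "")
  out <- data.frame(cdr3_aa = rep_cdr3, cdr3_length = nchar(rep_cdr3),
                    v_call = unname(vmaj[as.character(seq_len(nclone))]),
                    j_call = unname(jmaj[as.character(seq_len(nclone))]),
                    read_count = read_count, n_members = n_members,
                    stringsAsFactors = FALSE)
  # stable ids: by abundance, then representative CDR3
  ord <- order(-out$read_count, out$cdr3_aa)
  out <- out[ord, , drop = FALSE]
  out$clone_id <- seq_len(nrow(out))
  out$frequency <- out$read_count / sum(out$read_count)
  members <- split(u_all, u_clone)
  out$members <- lapply(members[as.character(seq_len(nclone))], sort)[ord]
  rownames(out) <- NULL
  out[, c("clone_id", "cdr3_aa", "cdr3_length", "v_call", "j_call",
          "read_count", "frequency", "n_members", "members")]
}

#' Filter clones by read support
#'
#' Removes clones supported by fewer than `min_reads` sequencing reads and
#' renormalizes the surviving clone frequencies.
#'
#' @param clones Clone table from [cluster_clones()].
#' @param min_reads Minimum read count (default 2).
#' @return Filtered clone table.
#' @export
filter_clones <- function(clones, min_reads = 2L) {
  keep <- clones$read_count >= min_reads
  out <- clones[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("all clones removed by the read-support filter")
    return(out)
  }
  out$frequency <- out$read_count / sum(out$read_count)
  rownames(out) <- NULL
  out
}

#' Write a clone table as TSV
#'
#' @param clones Clone table.
#' @param path Output file.
#' @export
write_clones <- function(clones, path) {
  drop <- vapply(clones, is.list, TRUE)
  write.table(clones[, !drop, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
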