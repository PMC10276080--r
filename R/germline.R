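#' IMGT framework/CDR region boundaries for V genes
#'
#' Half-open amino-acid intervals in IMGT numbering: FR1 = \[1,27),
#' CDR1 = \[27,39), FR2 = \[39,56), CDR2 = \[56,66), FR3 = \[66,105).
#' The second conserved cysteine sits at position 104 (last FR3 residue).
#'
#' @return Named list of length-2 integer vectors `c(start, end)`.
#' @export
imgt_v_regions <- function() {
  list(FR1 = c(1L, 27L), CDR1 = c(27L, 39L), FR2 = c(39L, 56L),
       CDR2 = c(56L, 66L), FR3 = c(66L, 105L))
}

# gapped nt length needed to cover IMGT positions 1..104
IMGT_V_GAPPED_NT <- 312L

#' Construct a germline V or J gene record
#'
#' @param name Allele identifier, e.g. `"IGHV4-34*01"`.
#' @param segment `"V"` or `"J"`.
#' @param seq_gapped Nucleotide string over `A,C,G,T,.`; IMGT-gapped for V
#'   genes (`.` marks gap positions), ungapped for J genes.
#' @param primer_mask_nt Number of 5' nucleotides excluded from mutation
#'   counting (PCR primer binding site); must be a multiple of 3.
#' @return An object of class `germline_gene` with fields `name`, `segment`,
#'   `seq_gapped`, `seq` (ungapped), `region_map` (V only) and
#'   `primer_mask_nt`.
#' @export
germline_gene <- function(name, segment = c("V", "J"), seq_gapped,
                          primer_mask_nt = 21L) {
  segment <- match.arg(segment)
  seq_gapped <- toupper(seq_gapped)
  bad <- gsub("[ACGT.]", "", seq_gapped)
  if (nzchar(bad)) {
    stop("germline record '", name, "' contains non-ACGT. characters: ",
         substr(bad, 1, 10))
  }
  seq <- gsub(".", "", seq_gapped, fixed = TRUE)
  region_map <- NULL
  if (segment == "V") {
    if (nchar(seq_gapped) < IMGT_V_GAPPED_NT) {
      stop("V record '", name, "' is shorter than the IMGT V region ",
           "(need ", IMGT_V_GAPPED_NT, " gapped nt through position 104, got ",
           nchar(seq_gapped), ")")
    }
    region_map <- imgt_v_regions()
  }
  if (primer_mask_nt %% 3L != 0L || primer_mask_nt > nchar(seq)) {
    stop("primer_mask_nt must be a multiple of 3 and <= ungapped length")
  }
  structure(list(name = name, segment = segment, seq_gapped = seq_gapped,
                 seq = seq, region_map = region_map,
                 primer_mask_nt = as.integer(primer_mask_nt)),
            class = "germline_gene")
}

#' @export
print.germline_gene <- function(x, ...) {
  cat(sprintf("<germline_gene> %s (%s), %d nt ungapped\n",
              x$name, x$segment, nchar(x$seq)))
  invisible(x)
}

#' Read an IMGT-style germline FASTA file
#'
#' V files may use IMGT gap characters (`.`); the allele name is taken from
#' the pipe-delimited header field that looks like an allele (contains `*`
#' or starts with `IG`/`TR`), falling back to the first field; headers
#' without pipes use the first whitespace-delimited token.
#'
#' @param path FASTA file.
#' @param segment `"V"` or `"J"`.
#' @param primer_mask_nt Passed to [germline_gene()].
#' @return Named list of `germline_gene` objects (a `germline_set`).
#' @export
read_imgt_fasta <- function(path, segment = c("V", "J"),
                            primer_mask_nt = 21L) {
  segment <- match.arg(segment)
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("empty FASTA file: ", path)
  headers <- names(recs)
  nm <- vapply(headers, function(h) {
    if (grepl("|", h, fixed = TRUE)) {
      f <- strsplit(h, "|", fixed = TRUE)[[1]]
      hit <- grepl("\\*", f) | grepl("^(IG|TR)", f)
      if (any(hit)) f[which(hit)[1]] else f[1]
    } else {
      strsplit(h, "[ \t]")[[1]][1]
    }
  }, "", USE.NAMES = FALSE)
  if (anyDuplicated(nm)) {
    stop("duplicate allele names in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  genes <- lapply(seq_along(recs), function(i) {
    germline_gene(nm[i], segment, as.character(recs[[i]]),
                  primer_mask_nt = primer_mask_nt)
  })
  names(genes) <- nm
  structure(genes, class = "germline_set")
}

#' Write germline genes back to FASTA (gapped sequence for V)
#'
#' @param genes A list of `germline_gene` objects.
#' @param path Output file.
#' @export
write_imgt_fasta <- function(genes, path) {
  seqs <- Biostrings::BStringSet(vapply(genes, `[[`, "", "seq_gapped"))
  names(seqs) <- vapply(genes, `[[`, "", "name")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Map an IMGT amino-acid region to ungapped nucleotide coordinates
#'
#' Converts a region's IMGT codon interval to a 0-based half-open
#' nucleotide interval on the gene's ungapped sequence, accounting for IMGT
#' gap positions.
#'
#' @param gene A `germline_gene`.
#' @param region Region id present in the gene's `region_map`
#'   (`"FR1"`, `"CDR1"`, `"FR2"`, `"CDR2"`, `"FR3"`).
#' @return Integer vector `c(start, end)`, 0-based half-open.
#' @export
codon_interval_to_nt <- function(gene, region) {
  if (is.null(gene$region_map) || !region %in% names(gene$region_map)) {
    stop("region '", region, "' is not defined for gene ", gene$name,
         if (gene$segment == "J") " (J genes carry no region map)")
  }
  iv <- gene$region_map[[region]]
  gp <- strsplit(gene$seq_gapped, "")[[1]]
  nongap <- cumsum(gp != ".")
  gstart <- 3L * (iv[1] - 1L)          # gapped nt offset, 0-based
  gend <- 3L * (iv[2] - 1L)
  start <- if (gstart == 0L) 0L else nongap[gstart]
  end <- nongap[gend]
  c(as.integer(start), as.integer(end))
}

# ungapped nt position where FR3 ends (end of the V region proper)
v_fr3_end_nt <- function(gene) codon_interval_to_nt(gene, "FR3")[2]

# IMGT position (1..104) of each ungapped codon of a V gene
imgt_codon_positions <- function(gene) {
  gp <- strsplit(gene$seq_gapped, "")[[1]][seq_len(IMGT_V_GAPPED_NT)]
  first <- gp[seq(1L, IMGT_V_GAPPED_NT, by = 3L)]
  which(first != ".")
}

# collapse allele name to gene level ("IGHV3-23*04" -> "IGHV3-23")
collapse_allele <- function(x) sub("\\*.*$", "", x)

#' @export
print.germline_set <- function(x, ...) {
  seg <- vapply(x, `[[`, "", "segment")
  cat(sprintf("<germline_set> %d genes (%d V, %d J)\n",
              length(x), sum(seg == "V"), sum(seg == "J")))
  invisible(x)
}

#' Path to the bundled synthetic germline reference
#'
#' A constructed (synthetic, not IMGT-derived) reference of 6 V and 3 J
#' genes with realistic naming, IMGT gap characters, conserved anchors and
#' pairwise nucleotide identity below 85%. Real IMGT reference files are
#' accepted by [read_imgt_fasta()] in the same way.
#'
#' @param segment `"V"` or `"J"`.
#' @return File path.
#' @export
synthetic_germline_path <- function(segment = c("V", "J")) {
  segment <- match.arg(segment)
  fn <- if (segment == "V") "synthetic_IGHV.fasta" else "synthetic_IGHJ.fasta"
  system.file("extdata", fn, package = "ighrep", mustWork = TRUE)
}
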