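#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' seeded subsampling does not perturb an enclosing simulation.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# deterministic 31-bit string hash (for per-sample seed derivation)
string_hash <- function(x) {
  v <- utf8ToInt(x)
  h <- 0
  for (i in v) h <- (h * 31 + i) %% 2147483647L
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# codon -> amino acid lookup built from the standard genetic code
codon_table <- local({
  gc <- NULL
  function() {
    if (is.null(gc)) gc <<- Biostrings::GENETIC_CODE
    gc
  }
})

# vectorized translation of many reads in a given frame (0-based);
# incomplete trailing codons dropped, ambiguous codons become X
batch_translate <- function(seqs, frame = 0L) {
  w <- nchar(seqs) - frame
  w <- pmax(w - (w %% 3L), 0L)
  sub <- substr(seqs, frame + 1L, frame + w)
  out <- character(length(seqs))
  nz <- which(w > 0L)
  if (length(nz)) {
    fuzzy <- grepl("[^ACGT]", sub[nz])
    if (any(!fuzzy)) {
      out[nz[!fuzzy]] <- as.character(Biostrings::translate(
        Biostrings::DNAStringSet(sub[nz][!fuzzy])))
    }
    if (any(fuzzy)) {
      out[nz[fuzzy]] <- as.character(suppressWarnings(Biostrings::translate(
        Biostrings::DNAStringSet(sub[nz][fuzzy]), if.fuzzy.codon = "solve")))
    }
  }
  out
}

# translate an in-frame nucleotide string; incomplete trailing codon dropped,
# codons with non-ACGT characters become X
translate_nt <- function(x) {
  vapply(x, function(s) {
    k <- nchar(s) %/% 3L
    if (k == 0L) return("")
    cods <- substring(s, 3L * seq_len(k) - 2L, 3L * seq_len(k))
    aa <- codon_table()[cods]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, "", USE.NAMES = FALSE)
}
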