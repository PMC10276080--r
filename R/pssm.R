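AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

JUNCTION_IDS <- c("FR1/CDR1", "CDR1/FR2", "FR2/CDR2", "CDR2/FR3",
                  "FR3/CDR3", "CDR3/FR4")

# ungapped aa position (0-based) of each V junction for one gene:
# anchor = index of the first residue after the junction
v_junction_anchors <- function(gene) {
  ends <- vapply(c("FR1", "CDR1", "FR2", "CDR2", "FR3"),
                 function(r) codon_interval_to_nt(gene, r)[2] %/% 3L, 0L)
  unname(ends)  # FR1/CDR1, CDR1/FR2, FR2/CDR2, CDR2/FR3, FR3/CDR3 anchors
}

# find the J-gene CDR3-end anchor: 0-based aa index of the first W of a
# WGxG motif, plus the reading frame in which it occurs
j_anchor <- function(gene) {
  for (f in 0:2) {
    aa <- translate_nt(substr(gene$seq, f + 1L, nchar(gene$seq)))
    m <- regexpr("WG.G", aa)
    if (m > 0) return(list(frame = f, w = as.integer(m) - 1L, aa = aa))
  }
  stop("no WGxG motif found in J gene ", gene$name)
}

pssm_matrix <- function(windows, pseudocount, background) {
  width <- nchar(windows[1])
  n <- length(windows)
  mat <- matrix(0, nrow = 21L, ncol = width,
                dimnames = list(c(AA20, "other"), NULL))
  chars <- matrix(unlist(strsplit(windows, "")), nrow = n, byrow = TRUE)
  for (k in seq_len(width)) {
    cnt <- table(factor(chars[, k], levels = AA20))
    p <- (as.numeric(cnt) + pseudocount) / (n + 20 * pseudocount)
    mat[seq_len(20L), k] <- log2(p / background)
    mat[21L, k] <- log2((pseudocount / (n + 20 * pseudocount)) /
                          mean(background))
  }
  mat
}

score_window <- function(mat, window) {
  ch <- strsplit(window, "")[[1]]
  idx <- match(ch, AA20)
  idx[is.na(idx)] <- 21L
  sum(mat[cbind(idx, seq_along(ch))])
}

#' Build framework/CDR junction PSSMs from germline references
#'
#' For each of the six junctions (FR1/CDR1, CDR1/FR2, FR2/CDR2, CDR2/FR3,
#' FR3/CDR3, CDR3/FR4) a log-odds matrix
#' `log2(((count + pseudocount) / (n + 20 * pseudocount)) / background)` is
#' built from the amino-acid windows flanking that junction across all
#' references (V genes for the first five, J genes for the last). Windows
#' that would extend past a reference are shrunk (with a warning) to the
#' largest width available in every reference.
#'
#' @param v_genes,j_genes `germline_gene` lists from [read_imgt_fasta()].
#' @param window_half_width Half-window width in amino acids (default 5).
#' @param pseudocount Additive pseudocount (default 1).
#' @param min_score_frac Acceptance threshold as a fraction of the lowest
#'   self-score (score of a training window) for each junction
#'   (default 0.6).
#' @param background Amino-acid background frequencies (default uniform).
#' @return A `junction_pssms` object.
#' @export
build_junction_pssms <- function(v_genes, j_genes, window_half_width = 5L,
                                 pseudocount = 1, min_score_frac = 0.6,
                                 background = rep(1 / 20, 20)) {
  stopifnot(length(v_genes) >= 1L, length(j_genes) >= 1L)
  w <- as.integer(window_half_width)
  v_aa <- lapply(v_genes, function(g)
    translate_nt(substr(g$seq, 1L, v_fr3_end_nt(g))))
  anchors <- lapply(v_genes, v_junction_anchors)
  pssms <- vector("list", 6L)
  names(pssms) <- JUNCTION_IDS
  for (jn in 1:5) {
    pos <- vapply(anchors, `[[`, 0L, jn)          # 0-based anchor per gene
    lens <- vapply(v_aa, nchar, 0L)
    lw <- min(w, min(pos))
    rw <- min(w, min(lens - pos))
    if (lw < w || rw < w) {
      warning("junction ", JUNCTION_IDS[jn], ": window shrunk to -",
              lw, "/+", rw, " aa to fit all references")
    }
    windows <- mapply(function(aa, p)
      substr(aa, p - lw + 1L, p + rw), unlist(v_aa), pos)
    mat <- pssm_matrix(windows, pseudocount, background)
    selfs <- vapply(windows, function(win) score_window(mat, win), 0)
    pssms[[jn]] <- list(junction = JUNCTION_IDS[jn], mat = mat, left_w = lw,
                        min_score = min_score_frac * min(selfs))
  }
  ja <- lapply(j_genes, j_anchor)
  jw <- vapply(ja, `[[`, 0L, "w")
  jlen <- vapply(ja, function(x) nchar(x$aa), 0L)
  lw <- min(w, min(jw))
  rw <- min(w, min(jlen - jw))
  if (lw < w || rw < w) {
    warning("junction CDR3/FR4: window shrunk to -", lw, "/+", rw,
            " aa to fit all references")
  }
  windows <- vapply(ja, function(x)
    substr(x$aa, x$w - lw + 1L, x$w + rw), "")
  mat <- pssm_matrix(windows, pseudocount, background)
  selfs <- vapply(windows, function(win) score_window(mat, win), 0)
  pssms[[6L]] <- list(junction = "CDR3/FR4", mat = mat, left_w = lw,
                      min_score = min_score_frac * min(selfs))

  # expected spacings between consecutive anchors (mean over V references)
  amat <- do.call(rbind, anchors)
  spacing <- colMeans(cbind(amat[, 1, drop = FALSE],
                            amat[, 2:5] - amat[, 1:4]))
  structure(list(pssms = pssms,
                 spacing = as.numeric(spacing),   # FR1 len, CDR1, FR2, CDR2, FR3
                 cdr3_span = c(3L, 28L),          # allowed W - FR3/CDR3 anchor gap
                                                  # (CDR3 of 5..30 aa incl. anchors)
                 window_half_width = w,
                 j_anchor_frames = vapply(ja, `[[`, 0L, "frame")),
            class = "junction_pssms")
}

#' @export
print.junction_pssms <- function(x, ...) {
  cat("<junction_pssms> 6 junction models, half-width",
      x$window_half_width, "aa\n")
  invisible(x)
}

#' Locate framework/CDR regions on reads via junction PSSMs
#'
#' Each read is translated in all three frames; every junction PSSM is slid
#' over each translation and the best-scoring anchor recorded. A frame is
#' accepted when the six anchors are strictly increasing, the V-junction
#' spacings are within `spacing_tol` of the germline expectation, the
#' FR3/CDR3 to CDR3/FR4 gap is a plausible CDR3 length, the translation is
#' stop-free through the CDR3 end, and the summed score reaches the
#' per-junction acceptance thresholds. Among accepted frames the one with
#' the highest total score wins.
#'
#' @param seqs Character vector of read nucleotide sequences.
#' @param pssms A `junction_pssms` object.
#' @param spacing_tol Relative tolerance on junction spacing (default 0.3).
#' @return Data.frame with one row per read: `frame` (0-2), anchor columns
#'   `a1`..`a6` (0-based aa positions in that frame's translation),
#'   `score`, `located` (logical).
#' @export
locate_regions <- function(seqs, pssms, spacing_tol = 0.3) {
  n <- length(seqs)
  res <- list()
  best_score <- rep(-Inf, n)
  out <- data.frame(frame = rep(NA_integer_, n), a1 = NA_integer_,
                    a2 = NA_integer_, a3 = NA_integer_, a4 = NA_integer_,
                    a5 = NA_integer_, a6 = NA_integer_,
                    score = NA_real_, located = FALSE)
  if (n == 0L) return(out)
  min_total <- sum(vapply(pssms$pssms, `[[`, 0, "min_score"))
  for (f in 0:2) {
    aa <- batch_translate(seqs, f)
    pos <- matrix(NA_integer_, n, 6L)
    sc <- matrix(NA_real_, n, 6L)
    for (jn in 1:6) {
      p <- pssms$pssms[[jn]]
      hit <- cpp_pssm_best(aa, p$mat, p$left_w)
      pos[, jn] <- hit$pos
      sc[, jn] <- hit$score
    }
    total <- rowSums(sc)
    ok <- !is.na(total) & apply(pos, 1L, function(x)
      !anyNA(x) && all(diff(x) > 0L)) & total >= min_total
    # spacing checks against germline expectations
    exp_sp <- pssms$spacing
    if (any(ok)) {
      d <- cbind(pos[, 1, drop = FALSE],
                 pos[, 2:5, drop = FALSE] - pos[, 1:4, drop = FALSE])
      sp_ok <- rowSums(abs(d - matrix(exp_sp, n, 5, byrow = TRUE)) >
                         spacing_tol * matrix(exp_sp, n, 5, byrow = TRUE)) == 0
      cdr3_gap <- pos[, 6] - pos[, 5]
      sp_ok <- sp_ok & cdr3_gap >= pssms$cdr3_span[1] &
        cdr3_gap <= pssms$cdr3_span[2]
      # no stop codon through the CDR3 end
      stops <- regexpr("*", substr(aa, 1L, pos[, 6] + 1L), fixed = TRUE) > 0
      ok <- ok & sp_ok & !stops
    }
    upd <- which(ok & total > best_score)
    if (length(upd)) {
      best_score[upd] <- total[upd]
      out$frame[upd] <- f
      out[upd, paste0("a", 1:6)] <- pos[upd, , drop = FALSE]
      out$score[upd] <- total[upd]
      out$located[upd] <- TRUE
    }
  }
  out
}

#' Extract the CDR3 amino-acid sequence from located regions
#'
#' The CDR3 string includes both anchors: the FR3-terminal cysteine
#' (IMGT 104) and the J-gene tryptophan of the WGxG motif. A CDR3 is valid
#' when it is at least 5 aa long and free of stop codons (`*`) and
#' untranslatable codons (`X`).
#'
#' @param seqs Read nucleotide sequences.
#' @param regions Output of [locate_regions()].
#' @return Data.frame with `cdr3_aa` (NA where not located) and
#'   `cdr3_valid`.
#' @export
extract_cdr3 <- function(seqs, regions) {
  n <- length(seqs)
  cdr3 <- rep(NA_character_, n)
  loc <- which(regions$located)
  if (length(loc)) {
    frames <- regions$frame[loc]
    aa <- character(length(loc))
    for (f in unique(frames)) {
      sel <- frames == f
      aa[sel] <- batch_translate(seqs[loc][sel], f)
    }
    cdr3[loc] <- substr(aa, regions$a5[loc], regions$a6[loc] + 1L)
  }
  valid <- !is.na(cdr3) & nchar(cdr3) >= 5L &
    !grepl("*", cdr3, fixed = TRUE) & !grepl("X", cdr3, fixed = TRUE)
  data.frame(cdr3_aa = cdr3, cdr3_valid = valid, stringsAsFactors = FALSE)
}
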