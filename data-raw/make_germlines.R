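# Builds the synthetic germline V/J reference bundled with the package.
# Constructed (not copied from IMGT): Ig-like framework scaffolding with
# conserved anchors (W41, C104, WGxG in J), variable CDRs, per-gene CDR
# lengths realised as IMGT '.' gaps, pairwise nt identity < 85%.
set.seed(20241024)

AA <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y")
# codon table (no stops)
GC <- Biostrings::GENETIC_CODE
syn <- split(names(GC), GC)
syn[["*"]] <- NULL

aa2codon <- function(aa_vec) {
  vapply(aa_vec, function(a) sample(syn[[a]], 1), "")
}

# IMGT region aa spans (1-based positions): FR1 1-26, CDR1 27-38, FR2 39-55,
# CDR2 56-65, FR3 66-104
region_len <- c(FR1 = 26, CDR1 = 12, FR2 = 17, CDR2 = 10, FR3 = 39)

v_names <- c("IGHV1-18*01","IGHV3-23*01","IGHV3-7*01","IGHV4-34*01",
             "IGHV4-39*01","IGHV5-51*01")

# framework scaffold: per position a pool of residues; positions flanking
# region boundaries are strongly conserved so junction PSSMs are informative
make_pool <- function(n, conserved_idx) {
  pool <- replicate(n, sample(AA, sample(3:5, 1)), simplify = FALSE)
  for (i in conserved_idx) pool[[i]] <- list(sample(AA, 1))[[1]]
  pool
}
fr1_pool <- make_pool(26, c(1:3, 22:26))      # conserved start + FR1/CDR1 flank
fr2_pool <- make_pool(17, c(1:4, 14:17))      # conserved CDR1/FR2 and FR2/CDR2 flanks
fr3_pool <- make_pool(39, c(1:4, 35:39))      # conserved CDR2/FR3 and FR3 end
fr2_pool[[3]] <- "W"                          # conserved W41 (FR2 pos 3)
fr3_pool[[39]] <- "C"                         # 2nd-CYS at IMGT 104

sample_fr <- function(pool) vapply(pool, function(p) sample(p, 1), "")

# per-gene CDR lengths (aa actually present; rest are IMGT gaps)
cdr1_len <- c(8, 10, 12, 8, 10, 12)
cdr2_len <- c(8, 10, 8, 10, 8, 10)

cdr_sample <- function(n) sample(setdiff(AA, c("C","W")), n, replace = TRUE)

gap_pad <- function(aa, full) {
  # IMGT convention: gaps go in the middle of the loop
  ng <- full - length(aa)
  left <- ceiling(length(aa) / 2)
  c(aa[seq_len(left)], rep(".", ng), aa[(left + 1):length(aa)])
}

v_gapped <- character(length(v_names))
for (g in seq_along(v_names)) {
  fr1 <- sample_fr(fr1_pool)
  if (v_names[g] == "IGHV4-34*01") fr1[23:25] <- c("A","V","Y")  # hydrophobic patch
  else fr1[23:25] <- sample(setdiff(AA, c("A","V","Y","C","W","*")), 3)
  cdr1 <- gap_pad(cdr_sample(cdr1_len[g]), 12)
  fr2 <- sample_fr(fr2_pool)
  cdr2 <- gap_pad(cdr_sample(cdr2_len[g]), 10)
  fr3 <- sample_fr(fr3_pool)
  aa <- c(fr1, cdr1, fr2, cdr2, fr3)
  stopifnot(length(aa) == 104)
  codons <- ifelse(aa == ".", "...", NA)
  codons[aa != "."] <- aa2codon(aa[aa != "."])
  v_gapped[g] <- paste(codons, collapse = "")
}

# J genes: in frame 0; tail (CDR3 part) then W + FR4 (WGxG motif)
j_names <- c("IGHJ4*01","IGHJ5*01","IGHJ6*01")
j_aa <- list(
  c("F","D","Y","W","G","Q","G","T","L","V","T","V","S","S"),
  c("N","W","F","D","S","W","G","Q","G","T","L","V","T","V","S","S"),
  c("Y","Y","Y","M","D","V","W","G","K","G","T","T","V","T","V","S","S")
)
j_seq <- vapply(j_aa, function(a) paste(aa2codon(a), collapse = ""), "")

# pairwise identity check on gapped V strings
idmat <- matrix(NA_real_, 6, 6)
for (i in 1:5) for (j in (i + 1):6) {
  a <- strsplit(v_gapped[i], "")[[1]]; b <- strsplit(v_gapped[j], "")[[1]]
  keep <- a != "." & b != "."
  idmat[i, j] <- mean(a[keep] == b[keep])
}
cat("max pairwise V identity:", max(idmat, na.rm = TRUE), "\n")
stopifnot(max(idmat, na.rm = TRUE) < 0.85)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
writeLines(as.vector(rbind(paste0(">X00000|", v_names, "|Homo sapiens|synthetic"),
                           v_gapped)),
           "inst/extdata/synthetic_IGHV.fasta")
writeLines(as.vector(rbind(paste0(">X00000|", j_names, "|Homo sapiens|synthetic"),
                           j_seq)),
           "inst/extdata/synthetic_IGHJ.fasta")
cat("written\n")
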