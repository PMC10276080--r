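---
title: "Heavy-chain repertoire analysis with ighrep: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heavy-chain repertoire analysis with ighrep: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ighrep)
```

## Overview

`ighrep` analyses IgG/IgM heavy-chain B-cell-receptor (BCR) amplicon
sequencing for two-cohort studies, for example hypogammaglobulinemia
patients who do or do not require immunoglobulin replacement therapy. The
pipeline runs per sample:

1. **Read QC** — expected-error filtering and random subsampling;
2. **Annotation** — framework/CDR boundary detection with junction PSSMs,
   translation, CDR3 extraction, V/J germline assignment by local
   alignment, germline identity, and per-region somatic-hypermutation
   (SHM) tallies;
3. **Clonotyping** — CDR3-based clone clustering with length-dependent
   mismatch thresholds and a read-support filter;
4. **Repertoire statistics** — clone counts, Hill diversity,
   oligoclonality, CDR3-length distributions, V/J usage;

and, across samples, **cohort inference**: per-gene differential usage
(Wilcoxon rank-sum with Benjamini-Hochberg correction), PCA of usage,
group comparisons of summary metrics, and all-by-all Pearson correlation
with pairwise-complete observations.

A bundled simulator generates two-cohort studies with a known ground
truth, which is how the package validates itself end to end.

## Read quality control

The expected number of sequencing errors in a read is
$E = \sum_i 10^{-Q_i/10}$ over its per-base Phred scores. Reads with
$E > 2$ are discarded; $E = 2$ exactly is kept (a $10^{-9}$ absolute
slack absorbs binary floating-point rounding, far below the filter's
discrimination scale). After filtering, up to 15,000 reads per sample are
drawn uniformly without replacement; reads are ordered by id before
sampling so the drawn multiset depends only on the seed and the id set.
`N` bases contribute their stated Phred error probability to $E$ and
count as mismatches downstream.

Paired-end merging is not part of the standard flow — the pipeline
consumes single (forward or pre-merged) reads — but a naive overlap
merger (`merge_read_pairs()`, minimum overlap 20 nt, mismatch rate at
most 10%, higher-quality base wins) is available.

## Region annotation

Framework/CDR boundaries follow IMGT numbering: FR1 spans amino-acid
positions 1–26, CDR1 27–38, FR2 39–55, CDR2 56–65, FR3 66–104, with the
second conserved cysteine at 104. V references are read IMGT-gapped
(`.` = gap); all internal coordinates are 0-based half-open on ungapped
sequences, with IMGT positions appearing only as region labels.

For each of the six region junctions (FR1/CDR1 … CDR3/FR4) a
position-specific scoring matrix is built from the amino-acid windows
flanking that junction across the references: log-odds
$\log_2\frac{(c + p)/(n + 20p)}{b}$ with pseudocount $p = 1$ and a
uniform background $b = 1/20$. The window half-width is 5 aa; windows
that would run past a reference (the FR3/CDR3 junction has no germline
right flank; short J tails limit the CDR3/FR4 left flank) are shrunk to
what every reference supports, with a warning. The acceptance threshold
per junction is 60% of the smallest training-window self-score. These
constants are not biologically forced; they were fixed once as
reproducible defaults anchored by the self-consistency requirement that
every training window passes its own PSSM, and they are exposed in
`pipeline_config()`.

A read is scanned in all three frames; the best-scoring anchor per
junction is accepted if anchors increase strictly, V-junction spacings
are within ±30% of the mean germline region lengths, the FR3/CDR3 →
CDR3/FR4 gap corresponds to a CDR3 of 5–30 aa, the translation is
stop-free through the CDR3 end, and the summed score meets the
thresholds. The CDR3 string includes both anchors — the FR3-terminal
cysteine (IMGT 104) and the J-gene tryptophan of the WGxG motif — so the
clonotyping length brackets below are defined on anchor-inclusive
lengths. A valid CDR3 is at least 5 aa with no stop or untranslatable
codon; reads without one are dropped from clonotyping and counted in the
attrition report. Hypermutation that creates a stop codon therefore
removes the read, exactly as a nonproductive rearrangement would be
removed from real data.

## V/J assignment and mutation profiling

Reads are aligned to every germline reference of a segment by affine
local (Smith-Waterman) alignment with match +1, mismatch −1, gap open −4,
gap extend −1 (a gap of length $L$ costs $4 + L$). Candidates need
nucleotide identity ≥ 50% (matches / aligned columns) and E-value
≤ 10⁻³; the winner has the lowest E-value, with ties broken by identity
and then gene name. E-values use the Karlin-Altschul form
$E = K m n e^{-\lambda S}$ with database size $n$ equal to the total
germline residues of the segment and $\lambda = 1.087$, $K = 0.093$,
estimated once for this scoring scheme by regressing the Gumbel tail of
2,000 random-pair alignment scores. Because $n$ is shared across
candidates, E-value ranking is exactly score ranking.

Two performance devices are used by default and can be switched off in
`alignment_params()`; both were verified to reproduce the exhaustive
full-matrix result on repertoire reads, and the aligner itself is tested
against `Biostrings::pairwiseAlignment` on random sequence pairs:

* a **diagonal band** (half-width 48 nt) for V alignments, exact whenever
  the read starts near the reference 5' end, as amplicons sequenced from
  a V-gene primer do (J genes match a read suffix and are never banded);
* an **8-mer candidate prescreen** in the spirit of USEARCH's word-count
  ordering: references sharing fewer than 60% of the best candidate's
  8-mers are skipped, and when the best candidate shares fewer than 16
  words every reference is aligned.

Identity is reported at the nucleotide level and, via codon-aware
translation of indel-free aligned codons, at the amino-acid level — both
always, since published analyses report either depending on isotype.

Mutation tallies count mismatches per aligned germline position, grouped
into FR1/CDR1/FR2/CDR2/FR3 by the reference's region map. The first
21 nt of the V gene (7 codons) are the PCR-primer binding site, where
mutations cannot be measured: these positions are excluded from mutation
counting (but not from identity, which summarizes the whole alignment).
Regions not covered by an alignment report zero aligned positions and an
undefined frequency — never a spurious zero mutation rate.
`positional_mutation_profile()` re-aligns the reads of one gene and
reports per-IMGT-position mutation frequencies, with a motif query (e.g.
the FR1 hydrophobic-patch AVY positions 23–25 of IGHV4-34) returning the
mean over the requested positions.

## Clonotyping

Unique CDR3 amino-acid strings are clustered within each length class:
pairs differing at ≤ 1 position (length 5–6 aa) or ≤ 2 positions
(length > 6 aa) are linked, and clones are the connected components
(single linkage), which fixes the transitive-chain behaviour the pairwise
rule leaves open; an exhaustive connected-components oracle pins this in
the tests. Distances are Hamming on equal lengths only — different
lengths never merge. Clustering conditions only on the CDR3 by default
(V/J calls are majority-vote metadata; `require_same_v` restricts merging
to a shared gene-collapsed V call). Clones supported by fewer than 2
reads are removed and frequencies renormalized. The representative CDR3
is the most abundant member, ties resolved lexicographically, making
clustering invariant to input order.

## Repertoire statistics

Hill (true) diversity is
$D_q = \left(\sum_i p_i^q\right)^{1/(1-q)}$, with
$D_1 = \exp(-\sum_i p_i \ln p_i)$; zero frequencies are ignored. The
package computes a panel $q \in \{0, 1, 2, 5\}$ and uses $q = 5$ as the
headline diversity index, following the default of the diversity function
in the tcR package that popularized this summary for repertoires; the
order used is always recorded in the output. Oligoclonality is the
cumulative frequency of the top 20 clones (100% when fewer clones exist).
CDR3-length histograms and medians and V/J usage are computed over
filtered clones (≥ 2 reads), with usage reported as percent of clones per
gene-collapsed name (alleles like `IGHV3-23*04` contribute to
`IGHV3-23`); genes absent from a sample appear with 0 so usage matrices
are complete. Usage is also computable at read level, but clone-level is
the default unit for comparisons.

## Cohort inference

All group comparisons use the two-sided Wilcoxon rank-sum test — exact
when the combined sample size is ≤ 25 without ties, otherwise the normal
approximation with tie and continuity corrections. Per-gene usage tests
are corrected by Benjamini-Hochberg within the set of genes tested for
one isotype (genes with zero usage everywhere are excluded from the
family). PCA transforms percent usage as $\log_2(x + 1)$ — the
pseudocount is applied on the percent scale — then centers columns;
components are sign-fixed so each component's largest-magnitude loading
is positive, and explained variance sums to 100%. Pearson correlations
between arbitrary per-sample features use pairwise-complete observations
with a two-sided t-test on $n_{pair} - 2$ degrees of freedom; pairs with
fewer than 3 complete observations or zero variance are undefined (NA),
and the significance mask blanks entries with $p > 0.05$. Germline
identity and mutation-frequency comparisons default to per-sample means
to avoid pseudo-replication; a pooled per-clone mode is available for
clone-level views.

## The simulator

`simulate_study()` generates a two-cohort study against the bundled
synthetic germline reference (6 V + 3 J genes; constructed sequences,
not IMGT data, with Ig-like conserved anchors — W41, C104, WGxG in J —
IMGT gaps realizing per-gene CDR lengths, and pairwise nucleotide
identity ≈ 50%). A clone is `V[FR1..FR3] + junction insert + J`: the
insert is uniform non-stop codons sized to a target CDR3 length drawn
from a discretized normal (mean 15 aa, sd 2, clamped to 5–30 aa,
anchors included), matching the median length of human heavy-chain
repertoires; the D segment is not modelled separately since only V and J
are assigned. SHM is applied as independent per-site substitutions at
region-specific rates — no indels (which would break the equal-length
clonotype rule) and no WRC/GYW hotspot structure. Read counts per clone
follow a power law in clone rank ($\propto r^{-\alpha}$), drawn as one
multinomial so they sum exactly to `reads_per_sample`. Per-base Phred
scores are a clamped normal; each base flips to a random other base with
probability $10^{-Q/10}$. Read ids encode donor and true clone for truth
joins. Donor $d$ seeds its RNG at `seed + 7919 d`, so studies are
reproducible byte for byte and adding a donor does not perturb others.

Two presets mirror the qualitative published contrasts:
`needs_igrt_like` (8 donors, 2,000 clones/donor, even clone sizes
$\alpha = 0.6$, low SHM ≈ 1–2%, IGHV4-34 sampling weight 3 vs 1) and
`no_igrt_like` (8 donors, 500 clones/donor, oligoclonal $\alpha = 1.2$,
higher SHM ≈ 3–5%, unbiased usage); both emit 15,000 reads/donor at
about Q40. These presets are the package's standing study conditions for
validation; the rates were chosen once to put germline identities in the
96–99% range typical of IgG/IgM repertoires.

What the simulator does **not** emulate — and hence what a passing test
suite does not establish about real data: sequencing indels and homopolymer
artefacts, primer and adapter contamination, chimeric PCR products, SHM
hotspot targeting and selection, clonal lineage structure (each clone is
one sequence), isotype-specific biology beyond the rate presets, and a
realistic allele-level germline repertoire (6 genes vs ~50+). Results on
real data additionally depend on the IMGT release used as reference,
which the user supplies through the same `read_imgt_fasta()` reader.

## Validation scale and numerical choices

The test suite validates formulas against independent brute-force
oracles (1,000 random instances each), clonotyping against exhaustive
connected components, and annotation against simulator truth (2,000
reads; 100% V-gene accuracy at zero SHM, ≥ 95% at 5%). End-to-end
recovery runs 20 replicate preset-contrast studies (8 vs 8 donors, 15,000
reads each) and requires each planted contrast — clone count, q = 5
diversity, top-20 cumulative frequency, IGHV4-34 usage, FR3 mutation
frequency — to reach p ≤ 0.05 (BH-adjusted for usage) in at least 80% of
replicates. Type-I calibration uses 20 parameter-identical null studies
at a reduced depth (300 clones, 3,000 reads per donor), sufficient
because the rank-sum test's level does not depend on read depth.
Determinism is asserted byte for byte, and subsampling a 30,000-read
sample to 15,000 under five different seeds must move the clone count by
less than 10% relative SD.

Degenerate inputs are defined rather than accidental: empty read sets
propagate as empty tables with zeroed reports; a sample yielding zero
clones is excluded from cohort statistics with a prominent warning; a
constant usage matrix has all-zero explained variance; undefined
correlations are NA, not errors; an all-singleton clone table filters to
an empty repertoire with a warning.

## Limitations

Beyond the simulator gaps above: D genes are not assigned and lineage
trees are not reconstructed; allele-level novel-gene discovery is out of
scope; the E-value calibration is specific to the default scoring scheme
(changing scores without re-estimating $\lambda, K$ changes E-values, not
ranking); and the PSSM junction finder assumes reads covering FR1 through
FR4, as amplicon protocols produce.
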