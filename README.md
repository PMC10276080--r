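# ighrep

Heavy-chain B-cell-receptor (BCR/IgH) repertoire analysis for two-cohort
studies: from raw amplicon FASTQ files to clone tables, diversity and
gene-usage statistics, and cohort-level inference. The package was built
for the kind of question asked in antibody-deficiency clinics — do
hypogammaglobulinemia patients who need immunoglobulin replacement
therapy carry systematically different IgG/IgM repertoires (more clones,
different V-gene usage, less somatic hypermutation) than patients who do
not? — but the pipeline applies to any two-group IgH amplicon study.

## What it computes

Per sample:

* **Expected-error QC**: discard reads with
  `E = Σᵢ 10^(−Qᵢ/10) > 2`, then randomly subsample up to 15,000 reads.
* **Annotation**: locate FR1–FR4 boundaries with junction PSSMs built
  from the germline references (IMGT numbering: FR1 1–26, CDR1 27–38,
  FR2 39–55, CDR2 56–65, FR3 66–104), translate, extract the CDR3
  (anchor-inclusive: C104 … J-tryptophan of the WGxG motif), assign V
  and J genes by affine local alignment (+1/−1, gap −4/−1; candidates
  need identity ≥ 50% and `E = K·m·n·e^(−λS) ≤ 10⁻³`; lowest E-value
  wins), and tally per-region mismatches with the first 21 nt (PCR
  primer site) masked.
* **Clonotyping**: merge CDR3s within 1 amino-acid difference (length
  5–6 aa) or 2 differences (length > 6 aa), single linkage, equal
  lengths only; keep clones with ≥ 2 reads.
* **Repertoire statistics**: clone count; Hill (true) diversity
  `D_q = (Σ pᵢ^q)^(1/(1−q))` for q ∈ {0, 1, 2, 5} (q = 5 is the headline
  index); top-20 cumulative frequency; CDR3-length histogram and median;
  percent V/J usage per gene.

Across cohorts: Wilcoxon rank-sum tests (exact for combined n ≤ 25
without ties) with Benjamini-Hochberg correction over the V genes tested,
PCA of `log2(percent usage + 1)`, and all-by-all Pearson correlation with
pairwise-complete observations (significance mask at p ≤ 0.05).

A **simulator** (`simulate_study()`, `cohort_preset()`) generates
two-cohort studies with ground-truth clone tables against a bundled
synthetic germline reference (6 V + 3 J constructed genes; real IMGT
FASTA files load through the same `read_imgt_fasta()`).

## Worked example

```r
library(ighrep)

# a small two-cohort study: 3 donors each, 2,000 reads per sample
a <- sim_cohort_config(label = "treated", n_donors = 3, clones_per_donor = 400,
                       clone_size_exponent = 0.6, reads_per_sample = 2000,
                       shm_rate_per_region = c(FR1 = .01, CDR1 = .02, FR2 = .01,
                                               CDR2 = .02, FR3 = .01, CDR3 = .02,
                                               J = .01),
                       seed = 1)
b <- sim_cohort_config(label = "untreated", n_donors = 3, clones_per_donor = 150,
                       clone_size_exponent = 1.2, reads_per_sample = 2000,
                       shm_rate_per_region = c(FR1 = .03, CDR1 = .05, FR2 = .03,
                                               CDR2 = .05, FR3 = .03, CDR3 = .05,
                                               J = .03),
                       seed = 2)
dir <- file.path(tempdir(), "study")
simulate_study(a, b, outdir = dir)

cfg <- pipeline_config(sample_sheet = file.path(dir, "sample_sheet.tsv"),
                       outdir = file.path(tempdir(), "results"))
res <- run_pipeline(cfg)

res$profiles[["treated_01"]]
#> <repertoire_profile> treated_01 (treated, IgG): 251 clones, D5 = 35.8, top-20 = 30.7%

profile_table(res$profiles)[, c("sample_id", "cohort", "n_clones",
                                "diversity_q5", "top_n_cumfreq")]
#>                 sample_id    cohort n_clones diversity_q5 top_n_cumfreq
#> treated_01     treated_01   treated      251    35.829050      30.74901
#> treated_02     treated_02   treated      263    46.061677      31.54912
#> treated_03     treated_03   treated      267    44.149842      29.46139
#> untreated_01 untreated_01 untreated       57     2.808949      88.53448
#> untreated_02 untreated_02 untreated       50     1.759796      89.41606
#> untreated_03 untreated_03 untreated       46     7.952558      83.69781

head(res$comparisons$IgG$group_summaries, 4)
#>          metric mean_treated mean_untreated statistic   p
#> 1      n_clones    260.33333       51.00000         9 0.1
#> 2  diversity_q5     42.01352        4.17377         9 0.1
#> 3 top_n_cumfreq     30.58651       87.21612         0 0.1
#> 4 v_identity_nt     98.93771       96.70572         9 0.1
```

Reading the output: the "treated" cohort was planted with more clones, a
more even clone-size distribution and less hypermutation, and the
pipeline recovers exactly that — ~260 vs ~51 clones, effective diversity
(number of equally common clones producing the same evenness) 42 vs 4.2,
and the top 20 clones holding 31% vs 87% of the repertoire. With 3
donors per arm, p = 0.1 is the smallest two-sided exact rank-sum p-value
attainable; the bundled 8-vs-8 presets reach p ≈ 1.6 × 10⁻⁴. The written
results directory additionally contains per-sample AIRR-style
rearrangement TSVs, clone tables, a QC/attrition report, differential
V-gene usage with adjusted p-values, PCA scores, and a JSON manifest of
every configuration constant and seed.

A thin command-line wrapper ships in `inst/scripts/ighrep`
(`simulate`, `qc`, `annotate`, `clonotype`, `stats`, `compare`,
`correlate`, `run-all`).

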