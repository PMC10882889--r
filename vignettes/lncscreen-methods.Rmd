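---
title: "lncscreen: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncscreen: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncscreen)
```

This vignette documents the models and procedures implemented in
`lncscreen`, the parameters that matter, the choices made where the design
was genuinely open, and what the synthetic-data validation does and does not
demonstrate.

## The discovery cascade

The pipeline consumes two exon-structured annotations: a *reference* (the
known transcriptome) and an *assembled* set (e.g. de-novo transcript models
from short-read assembly). Candidate novel lncRNAs are what survives three
stages:

1. **Novelty exclusion** (`exclude_known()`): a transcript is "known" if its
   genomic footprint overlaps any reference gene interval by at least 1 bp.
   Whether overlap should be judged at the exon or the whole-span level, and
   whether it should respect strand, is genuinely underdetermined in
   practice. We default to *gene span, strand-agnostic* — the most
   conservative (most-excluding) reading, which minimizes false novelty at
   the cost of discarding antisense candidates; both choices are exposed
   (`overlap = "exon"`, `stranded = TRUE`).
2. **Structural filtering** (`filter_structure()`): multi-exonic models with
   summed exon length strictly greater than 200 nt and at least one intron
   strictly longer than 10 nt. The strict inequalities matter at the
   boundaries: a 200-nt two-exon model and a model whose only intron is
   exactly 10 nt are both rejected, and the unit tests pin this down.
   Mono-exonic models are excluded outright as likely transcriptional
   noise.
3. **Isoform merging** (`merge_isoforms()`): loci are the connected
   components of the exonic-overlap graph (single linkage, same strand;
   unknown strand `"*"` bridges either). Merged models take the union of
   member exons with overlapping exons coalesced. The partition is verified
   against a brute-force BFS over an explicit adjacency matrix.

### Coding potential

Dedicated coding-potential tools are trained black boxes; `lncscreen`
instead uses a transparent two-channel rule that is fully testable:

* **ORF channel**: fires when the longest *complete* ORF (ATG through stop,
  over all six frames; N bases break ORFs; ORFs without an in-frame stop do
  not count) is ≥ 300 nt — the classical 100-codon convention — or when the
  ORF covers ≥ 50 % of the transcript *and* the Fickett TESTCODE score is
  ≥ 0.95, the published TESTCODE threshold for a confident coding call. The
  TESTCODE statistic is implemented from the published position/composition
  lookup tables (`fickett_score()`).
* **Domain channel**: fires when any user-supplied protein motif occurs as
  an exact substring of one of the six translated frames. This is a
  deliberately simple stand-in for a profile-HMM domain search, adequate
  for the classifier's role of flagging *conflicting* evidence.

Both channels positive → `coding`; both negative → `ncRNA`; exactly one →
`TUCP` (transcript of unknown coding potential). Every candidate gets
exactly one label, so the three classes partition the candidate set.

## Differential expression and conservation

`compare_conditions()` works on condition means of FPKM (or TPM) values. A
gene is droppable only when its mean is below the floor (default 0.2 FPKM)
in *both* conditions. The log2 fold change is `log2((mean_B + ε)/(mean_A +
ε))` with ε = 0 by default: when one mean is exactly zero the fold change is
±∞ and is treated as passing any finite cut. We prefer propagating the
infinity over silently damping it with a pseudo-count, because a planted
all-or-nothing gene *should* be called; a nonzero ε is available for noisy
count-derived data.

`select_de()` uses strict cuts (default |log2FC| > 1); `intersect_conserved()`
requires the same direction in every comparison — a gene up in two
comparisons and down in the third is excluded entirely. `prevalence_rank()`
calls a gene expressed in a patient when its value is strictly above the
floor and keeps genes expressed in strictly more than 90 % of patients,
ranking them by ascending mean expression. `threshold_de_table()` filters a
supplied statistics table at |log2FC| > 0.58 (1.5-fold) and FDR < 0.05,
computing Benjamini–Hochberg adjusted p-values when the table has none
(BH is the field default when a procedure is not specified).

## Cohort statistics and the correlation null

`fpkm_to_tpm()` rescales each sample by its total (columns sum to 10⁶
exactly, and the map is idempotent). `preprocess_cohort()` strips version
suffixes from gene ids, removes duplicated ids (first kept by default), and
retains one specimen per patient (lowest specimen order).

The centerpiece is `correlation_null()`: the Spearman correlation of a focal
gene pair is situated against an empirical null of 2000 random genes split
into 10 disjoint sets of 200. For each set we compute the correlations of
each focal gene with all 200 random genes, and report

* a Z-score `(ρ_pair − mean)/sd` per set, and
* the rank of ρ_pair among the 200 correlations (rank 1 = highest),

averaged across sets. Two details were open and are configurable: the Z
denominator (per-set sd by default, pooled sd by flag) and tie handling in
the rank (count-of-strictly-larger by default, average rank by flag).
Constant genes (zero rank variance) are excluded from the sampling pool with
a message, since their correlation is undefined. Sampling is without
replacement across the union of sets and excludes the focal pair; the whole
computation is seed-deterministic.

Under full independence the focal-pair Z behaves like a standard normal
(the per-set Zs are strongly correlated because they share the numerator, so
their mean keeps unit-like spread); the validation checks |mean z| < 0.1 and
sd within [0.85, 1.15] over 200 replicates of a 2500-gene × 366-sample
cohort, and that a planted ρ = 0.4 pair ranks in the top 2 in at least 9 of
10 sets.

`group_compare()` reports median, quartiles, whiskers at the furthest value
within 1.5×IQR of the quartiles, the mean, and a two-sample t-test. The
classical equal-variance form is the default because that is what "Student's
t-test" denotes; Welch is a flag.

## Kinome profiling

The plate model: each well starts with 250 nM ATP; kinases in the sample
consume ATP while phosphorylating the well's peptide sensor; the revealing
reagent produces luminescence proportional to *remaining* ATP. ATP-standard
wells at known concentrations give the calibration line (least squares;
positive slope required — a non-positive slope means a failed plate), whose
inverse converts any well to remaining ATP. Consumed + remaining = 250 nM
per well by construction.

Peptide activity is consumed ATP minus the consumption of the *matched
no-peptide well of the same sample*, removing sample-autonomous ATP use.
No-sample wells should read full ATP and no-ATP wells the luminescence
offset; both serve as QC only and do not enter the activity formula.
Replicate wells are averaged before profiling. Kinase activity is the
unweighted mean of the kinase's measured peptide sensors — the minimal
defensible aggregation when the sensor weighting of the original assay
platform is unavailable; a median flag exists. Kinases with fewer than
3 measured sensors are not reported.

Clustering uses the uncentered correlation distance
`1 − Σxy/√(Σx²·Σy²)` with average linkage (UPGMA), executed through
`stats::hclust` on a distance matrix computed in-package. Uncentered
correlation is scale-invariant but, unlike Pearson, not shift-invariant —
appropriate when the zero point (no activity) is meaningful. Zero vectors
have undefined similarity and are assigned the maximal distance 1 to every
item, deterministically. The implementation is checked against a brute-force
O(n³) UPGMA that recomputes cluster distances as means of original pairwise
distances; on continuous data ties have probability zero, so the cophenetic
matrices must agree to round-off.

`compare_signatures()` expresses two treatment signatures as log2 ratios to
a matched control signature over the shared kinases and reports their
Pearson correlation; a constant ratio profile (e.g. comparing the control to
itself) is an error rather than a silent NA.

## Pharmacology analytics

* **Combination index**: `CI = log2(E_ab / (E_a·E_b))` with E as
  control-normalized surviving fractions; CI = 0 at Bliss independence,
  CI < 0 synergy. Some printed protocol versions carry a minus sign in the
  denominator; for positive survival fractions that form has no real
  logarithm and contradicts the stated "< 0 means synergy" criterion, so the
  package adopts the positive-denominator form and keeps the literal one
  behind `strict_sign = TRUE` to document the convention.
* **Comparative Ct**: ΔCt per sample against the housekeeping gene, ΔΔCt as
  the difference of group means, fold = 2^(−ΔΔCt). Amplification efficiency
  is assumed to be exactly 2 per cycle (no efficiency correction), which is
  what the plain comparative-Ct method means.
* **N/C enrichment**: raw nuclear/cytoplasmic ratio `2^(Ct_cyto − Ct_nuc)`
  per transcript, normalized to the raw ratio of a nuclear control
  transcript. No housekeeping normalizer is used across fractions — a
  single housekeeping gene cannot calibrate two differently recovered
  fractions; the nuclear control ratio is the correct normalizer.
* **Tumor volume**: `0.5·L·W²`; by caliper convention length ≥ width, and
  measurements supplied the other way round are swapped with a warning
  (disable with `swap_axes = FALSE`).
* **t-test**: classical pooled-variance two-sided test; both-groups-constant
  input yields an undefined t (NaN) for equal means, ±∞ with p = 0
  otherwise.

## The synthetic-data generator

`sim_config()` fixes the conditions all validation runs under; a fixed seed
yields bit-identical artifacts. What each generator emulates:

* `gen_annotation()`: one synthetic chromosome (10 Mb default — enough
  intergenic space for interval logic without heavy objects), 50 two-exon
  reference genes each shadowed by an overlapping assembled transcript,
  5 planted three-exon lncRNAs (653 nt, introns 149/199 nt), and 30 noise
  transcripts cycling through three single-violation classes: mono-exonic
  (501 nt), exactly 200 nt total (rejected by the strict > 200 rule), and
  all-introns-≤ 10 nt. Each noise class passes the other two filters, so
  every filter is individually load-bearing in the end-to-end test.
* `gen_expression_cohorts()`: log-normal FPKM (Gaussian on log2 scale,
  default sd 0.3 — a realistic replicate CV for bulk RNA-seq FPKM), baseline
  log2 means uniform on [1, 6], 40 planted DE genes (20 up/20 down) shifted
  by ±2 log2 units in every non-baseline condition, 6 samples per condition.
  One gene pair is generated with Spearman ρ = 0.4 via a Gaussian copula
  (Pearson `2·sin(πρ/6)` on latent normals); the pair's variation rides on
  the unit log2 scale rather than on `noise_sd`, so the pair remains
  well-defined even at zero noise and the planted ρ is not attenuated.
* `gen_kinase_plate()`: luminescence = 4·[ATP remaining] + 100 RLU, peptide
  consumptions uniform on [20, 120] nM, sample backgrounds on [5, 20] nM,
  planted kinase effects multiply the peptide-specific consumption in
  treated samples, and noise is Gaussian with CV 2 % on luminescence —
  a plausible plate-reader figure. The zero-noise round trip through
  calibration, background correction and aggregation recovers planted
  effects to machine precision.
* `gen_viability_grid()`: Hill single-agent curves, combined survival =
  product of single-agent survivals × 2^`bliss_deviation`, so the downstream
  mean CI equals the planted deviation exactly at zero noise.
* `gen_ct_table()`: folds enter as Ct shifts of −log2(fold) in the treated
  group; N/C ratios as `Ct_nuc = Ct_cyto − log2(ratio)`.

### What passing tests do and do not show

The generator plants exactly the structure each stage is designed to
detect, under clean noise models (log-normal expression, Gaussian plate
noise, no batch effects, no read-level artifacts, no dropout structure,
independent genes apart from the planted pair). Passing therefore
demonstrates *correctness of the computations and calibration of the
statistics under their stated assumptions* — not robustness to assembler
artifacts, batch structure, heavy-tailed expression, or correlated gene
networks in real cohorts. External-cohort analyses (TCGA/GTEx-scale) use
the same code paths but are not exercised by the shipped tests, which run
entirely on synthetic data.

### Problem sizes used in validation

Chosen once as the package's validation conditions: annotation bundles of
85 assembled transcripts; 20 seeded three-comparison designs with 2000
genes; 200 correlation-null replicates at 2500 genes × 366 samples; 100
random 8 × 8 clustering instances against the brute-force oracle; 100 noisy
plate simulations; 100 noisy viability grids; 500 global-null DE tables;
10⁴ t-test replicates.

## Known limitations

* The coding-potential rule is a transparent surrogate, not a trained
  classifier; its thresholds (300 nt, 0.5 coverage, 0.95 TESTCODE) are
  conventional rather than optimized, and the motif channel does only exact
  substring matching.
* `exclude_known()` judges overlap on gene *spans* by default, so novel
  transcripts inside long introns of known genes are discarded unless
  `overlap = "exon"` is chosen.
* Kinase aggregation ignores sensor-specific weights and cross-reactivity;
  activities are comparable within a plate, not across platforms.
* The correlation null samples genes, not gene sets matched for expression
  level; strong mean-variance coupling in real data can make random-gene
  nulls conservative or liberal depending on the focal genes' abundance.
* No count-model DE estimation is included; `threshold_de_table()` expects
  statistics from an upstream tool.
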