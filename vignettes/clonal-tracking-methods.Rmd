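---
title: "Methods: clonal tracking and genomic dynamics of multi-organ metastasis"
author: "clonetrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonal tracking and genomic dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetrace)
```

# Overview

`clonetrace` implements the computational stages of a barcode-mediated
clonal-tracking study of metastasis in patient-derived xenograft (PDX)
models: tumor cells are labeled with a high-complexity lentiviral DNA
barcode library, engrafted into the mammary fat pad (MFP) of recipient
mice, and the barcode content of the primary tumor and of individually
dissected lung, liver and brain metastases is read out by amplicon
sequencing. Around that core the package adds the companion genomic
analyses such a study uses: single-hit limiting-dilution estimation of
metastasis-initiating frequency, mutant-allele-frequency (MAF) dynamics
between primary tumors and metastases, and a robustness filter for
mutation clusters produced by MCMC clustering of variants.

Every stage can be exercised on synthetic data from the bundled
generator, which records complete ground truth, so the package is fully
testable without any external sequencing data.

# Barcode quantification

## Read model

Each amplicon read is expected to be 40 bp: an 18 bp half-barcode,
the 4 bp spacer `TTCG` at positions 19–22 (1-based, inclusive —
all coordinates in this module are 1-based), and a second 18 bp
half-barcode at positions 23–40. The clone label is the *ordered pair*
of half-barcodes, drawn from the Cartesian product of two half-barcode
reference sets; with two ~13,000-sequence half-libraries the pair space
exceeds 10^8, which is what makes single-cell labeling at scale
possible.

Quantification proceeds in three stages, each conserving reads
(kept + dropped = input, tallied in a JSON-able log):

1. **Spacer filter** (`spacer_filter`): keep reads of length ≥ 40 whose
   positions 19–22 are within Hamming distance 1 of `TTCG`. Reads
   longer than 40 bp are truncated to their first 40 bases (adapter
   remnants); shorter reads are rejected. `N` counts as a mismatch.
2. **Split** (`split_reads`): positions 1–18 and 23–40.
3. **Alignment and paired counting** (`align_half`, `count_pairs`): each
   half must align *uniquely* to the half-library; reads whose two
   halves both align uniquely are counted as a pair, everything else is
   discarded and logged. Counts are normalized per sample to counts per
   million, CPM_i = Counts_i / ΣCounts × 10^6.

## The end-anchored mismatch rule

The alignment tolerance — "1 bp mismatch at either end" — admits two
readings: a single mismatch restricted to the terminal bases, or a
single mismatch anywhere. We implement the literal end-anchored
reading as the default: a half matches a library sequence at Hamming
distance 0, or at distance exactly 1 when the mismatch sits at the
first or last base. Because the original aligner invocation is not
fully specified, `mismatch_anywhere = TRUE` switches to the relaxed
reading; both paths return `ambiguous` whenever more than one library
sequence attains the minimal distance, and ambiguous halves are
discarded rather than rescued. Tests verify the fast implementation
against an exhaustive distance-scan oracle over every possible
single-base perturbation of every library sequence.

# Clonal-architecture metrics

* **Dominant barcodes** (`dominant_set`): sort barcodes by CPM
  descending and take the smallest prefix whose cumulative CPM reaches
  95% of the total. The boundary rule — whether the barcode that
  crosses the threshold is included — is not fixed by the definition of
  a "top 95%" set; we include it (the prefix is the *smallest* set that
  *reaches* 95%), break CPM ties by barcode id for determinism, and
  expose `include_crossing = FALSE` for the alternative.
* **Shannon diversity** (`shannon_diversity`): H = −Σ p_i ln p_i in
  nats over all detected barcodes, the standard measure of intra-tumoral
  clonal heterogeneity here.
* **Seeding clones** (`seeding_clones`): any barcode detected (≥ 1
  read by default; the floor is configurable for sensitivity analyses)
  in both a metastasis and its matched MFP tumor. Requiring MFP
  confirmation is what controls false positives among rare metastasis
  barcodes, so no abundance cutoff is applied. Barcodes are never
  compared across mice — each mouse receives an essentially disjoint
  barcode draw — and cross-mouse comparisons are refused with an error.
* **TIC frequency** (`tic_frequency`): percent of reference-pellet
  barcodes re-detected in the grown tumor.
* **Overlap and distribution summaries**: Jaccard indices between
  dominant sets, log10-CPM histograms, and the per-mouse maximum CPM a
  barcode attains across that mouse's samples.
* **Group comparisons** (`group_compare`): two-tailed t-tests on
  per-sample statistics. The variance assumption is not fixed by
  "two-tailed t-test"; we default to Welch (the safer choice under
  unequal group sizes and variances) with `var_equal = TRUE` available.

`clonal_report` ties these together per sample, per metastasis (with
percent-dominant-of-MFP and percent-seeding-of-MFP computed relative to
the unique barcode count of the matched MFP tumor), and per mouse,
refusing any metastasis whose mouse lacks exactly one MFP sample.

# Limiting-dilution estimation

Under the single-hit Poisson model a transplant of `d` cells is
positive with probability `1 − exp(−f·d)`, where `f` is the frequency
of cells able to initiate the scored outcome (a metastasis, for the
assays bundled here). `fit_single_hit` maximizes

```
l(f) = Σ_rows [ y·log(1 − e^(−f·d)) − f·d·(n − y) ]
```

by solving the score equation with bisection on a bracketing interval
(tolerance 1e−12); the estimate provably equals the grid/golden-section
argmax, and a complementary-log-log binomial GLM with log-dose offset
reproduces it to the GLM's own convergence tolerance (both are test
oracles). The default 95% interval is Wald on log(f) using the expected
(Fisher) information — the convention of the standard extreme
limiting-dilution analysis tools — with a profile-likelihood interval
behind `ci = "profile"`.

Degenerate tables get one-sided answers rather than forced fits: with
no positives the upper bound solves `exp(−f·Σ d·n) = 0.05`; with no
negatives a lower bound solves the mirrored equation; both are flagged.
Estimator calibration (`recover_from_simulation`) simulates assays at a
known `f` and reports bias and empirical CI coverage; at `f = 0.1` on a
6×(100, 10, 1)-cell design the Wald interval's coverage sits within
[0.90, 0.99] over 1000 simulations.

One bundled table is a known discrepancy: the single-hit MLE on the
liver assay counts (100 cells: 1/3; 10 cells: 2/3) is 1.2%, not the
2.1% historically reported alongside them. The package reports the MLE
and leaves the difference documented rather than reconciled; the liver
assay is therefore a worked example, not a reference value.

# MAF dynamics

`consensus_filter` applies the platform-specific elimination rules
(whole-exome: single-caller variants, total coverage < 30 in all
samples, alternate coverage < 5 in all samples, germline VAF ≥ 1%,
population-database presence, silent/intergenic/intronic; targeted:
≥ 2 callers in ≥ 1 sample and ≥ 3 mutant reads for per-sample
detection; barcoded targeted additionally ≥ 100× coverage). MAF is
always alt/(ref+alt); zero-coverage MAFs are undefined and flagged,
never imputed as 0.

`delta_maf` computes, per variant, the mean MAF across metastases minus
the mean across primaries, with a Welch two-tailed t-test; a variant is
*enriched* when ΔMAF ≥ 0.15 with p ≤ 0.05 (*depleted* mirrored). The p
threshold is deliberately unadjusted — the classification couples an
effect-size floor with a per-variant significance screen, and the
effect-size floor is what carries the specificity (tests show a
false-enrichment rate ≤ 0.05 for clonal mutations at depth 1500).

`de_novo_candidates` implements the de novo criteria: zero alternate
reads by WES *and* fewer than 7 mutant reads by targeted deep
sequencing in every MFP tumor, plus detection in metastases of exactly
one mouse — the same mutation arising independently in several mice is
treated as implausible.

`repeat_artifact_filter` targets alignment artifacts from repeat
regions, which manifest as pairs of mutations co-occurring on the same
reads. Each pair's 2×2 read table gets a Pearson chi-square test of
independence without continuity correction (Fisher's exact test when
any expected cell is below 5 — the chi-square approximation is poor
there and the choice is configurable), Benjamini–Hochberg adjustment
across pairs, flagging at q < 0.05, and discarding — both members —
when the pair additionally co-occurs in over 1% of its spanning reads.
"1% of the reads" is interpreted as the reads spanning the pair (the
only total the pair's table defines); the filter's type-I error is
verified ≤ 0.06 on 10,000 simulated independent pairs.

`human_fraction` is the qPCR delta-Ct partition
`100·2^(−ΔCt,human) / (2^(−ΔCt,human) + 2^(−ΔCt,mouse))`, used to
triage xenograft samples by human DNA content. `sample_similarity`
gives pairwise Pearson correlations over shared defined MAFs and
complete-linkage clustering on Euclidean distances.

# Cluster-stability testing

MCMC clusterings of variants (e.g. Dirichlet-process mixtures over
allele counts) can emit clusters whose members wander between labels
across iterations. `coassignment_matrix` computes, after burn-in
(default 2500 iterations of a 10,000-iteration trace), the probability
that each variant pair shares a label. Within each candidate cluster —
the modal post-burn-in assignment per variant, ties to the smallest
label — pair probabilities are binned as high (0.9 ≤ p ≤ 1), low
(0.5 ≤ p < 0.9), and below (p < 0.5); the published discretization
defines only the two upper bins, and the third makes the partition
total so a goodness-of-fit test is well defined.

The "random" baseline against which a cluster's category counts are
tested is not defined by the procedure's description; we estimate it
from the category frequencies over *all* unordered variant pairs in the
trace (`baseline = "uniform"` is the documented alternative). Each
cluster's chi-square goodness-of-fit p-value is Bonferroni-corrected
over the number of testable clusters, robustness requires adjusted
p < 0.05, and categories with zero expectation are merged (below into
low) and logged. Calibration over 200 simulated traces (stable clusters
flipping at rate 0.05, unstable at 0.45) shows recall ≥ 0.95 for stable
clusters and a false-robustness rate ≤ 0.05.

# The synthetic-data generator

`simulate_experiment` emulates the study design per mouse:

* integrants per cell ~ Poisson(MOI), MOI 0.2, so ~18% of cells are
  labeled and the vast majority of labeled cells carry one integrant;
  unlabeled cells are excluded. Labeled cells draw one barcode pair
  uniformly from the half-library squared (multi-integrant cells are
  collapsed to a single pair; at MOI 0.2 they are ~2% of labeled cells
  and nothing downstream consumes per-cell multi-barcode structure);
* engraftment is Bernoulli per clone with p_TIC = 0.04, the ~4%
  engraftment bottleneck observed in the tracked cohort;
* per-clone MFP abundance is negative-binomial (mean 50, dispersion
  0.5 by default), matching the overdispersed barcode distribution of
  reference cell pellets; dispersion is configurable;
* each lesion draws a configurable number of seeders (default 300,
  polyclonal seeding of a few hundred clones) without replacement with
  probability ∝ abundance^α (α = 1 by default — no seeding model is
  prescribed by the data, so proportional sampling is the neutral
  choice and α is exposed);
* each mouse has a small dominant set (default 5 clones, emulating the
  ≤ 10 dominant barcodes per mouse) drawn from the low-abundance half
  of the MFP and boosted by a dominance factor (default 500) in every
  lesion of that mouse — dominance shared across a mouse's lesions is
  the central observed phenomenon;
* reads are multinomial over lesion abundances: half1 + `TTCG` + half2
  with iid substitution errors (default rate 0.001/base) plus a junk
  fraction (default 5%) of uniform random 40-mers.

Every draw is reproducible from `(params, seed)`, and the returned
ground truth (clone pairs, engraftment, abundances, per-lesion seeding
and dominant sets, per-sample true read counts) is what the test suite
checks recovery against: with error rate 0 and junk 0 the
quantification round trip is *exact* per read.

What the generator does **not** emulate: PCR amplification bias and
duplicate structure, copy-number effects on barcode read-out, spatial
structure within lesions, cross-metastasis seeding, and clone-level
phenotype differences beyond the dominance boost. Passing tests
therefore demonstrate correctness of the computations under the stated
statistical model, not robustness to those real-data artifacts.

`subclone_phantom`/`simulate_maf_table` provide the variant-level
counterpart: a binary genotype × subclone matrix, per-sample mixing
proportions, and binomial read sampling at
μ = Σ genotype·mixing·0.5 — the heterozygous-diploid convention;
copy-number effects on MAF are out of scope.
`simulate_assignment_trace` flips each variant to a uniformly random
other cluster with a per-cluster rate, giving closed-form co-assignment
expectations ((1−q)² + q²/(K−1) within clusters) used as test oracles.

# Numerical choices and degenerate inputs

* Dominance prefix: cumulative CPM compared to the threshold with a
  1e−9 absolute slack so exact-boundary cases (uniform columns) are
  stable in floating point; ties broken by barcode id.
* Score-equation root: bisection to 1e−12 on (1e−12, 1]; a likelihood
  still increasing at f = 1 returns a flagged boundary estimate.
* Zero-variance t-test inputs return t = 0, p = 1 (equal means) or
  p = 0 (unequal) instead of erroring.
* Empty samples: CPM of a zero-count column is emitted as zeros with a
  warning flag in the log (not NaN); `dominant_set` and
  `shannon_diversity` refuse all-zero input.
* Co-occurrence pairs with an all-zero margin are untestable and
  logged, not errors.
* All randomized operations take explicit integer seeds; the pipeline
  derives per-stage child seeds from the global seed.

# Problem sizes used by the test suite

Simulation-based checks are sized to make their statistical
tolerances meaningful while keeping the default suite fast: the
engraftment check labels ~3×10^5 clones; dominant-clone recovery uses
two mice at 10^5 reads per sample with the default error and junk
rates; the delta-MAF classifier runs 100 phantom seeds at depth 1500
(3 primaries vs 6 metastases); the artifact filter's type-I check uses
10^4 independent pairs; CI coverage uses 1000 simulated assays; and
cluster-stability calibration uses 200 traces of 36 variants × 1000
iterations.

# Known limitations

* The end-anchored alignment rule is an interpretation; runs intended
  to mirror a historical pipeline exactly should evaluate both
  `mismatch_anywhere` settings.
* The liver limiting-dilution value discussed above is not reproduced
  by the single-hit MLE on its own counts.
* The cluster-stability baseline ("random") and the handling of
  below-0.5 pairs are interpretations, exposed as options.
* At very heavy-tailed clone-size dispersion the simulated max-CPM
  distribution need not be bimodal: the dominance boost multiplies a
  dominant clone's own (low) MFP abundance, so an extreme ordinary
  seeder can approach a weakly-seeded dominant clone. Dominant-clone
  *recovery* into top-95% sets is unaffected.
* Quality scores are ignored by design; there is no UMI logic, no
  genome alignment, no variant calling, and no copy-number estimation —
  upstream tools own those steps.
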