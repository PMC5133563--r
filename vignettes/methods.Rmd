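---
title: "Predicting lysine malonylation sites from primary sequence: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting lysine malonylation sites from primary sequence: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(malsite)
```

## The problem

Lysine malonylation is an acidic post-translational modification: a
malonyl group attached to a lysine side chain, implicated in metabolic
regulation and disease. Identifying modified sites by mass spectrometry is
slow and expensive, so sequence-based prediction — given a protein, which
of its lysines are plausible malonylation sites? — is a useful screen.
`malsite` implements such a predictor as a tested library plus a command
line, together with a synthetic-data generator so that every stage of the
pipeline can be exercised and validated without any external downloads.

## Peptide windows

Each candidate site is represented by the sequence context of its lysine:
a window of `xi = 6` residues upstream and `eta = 9` downstream, a 16-mer
with the lysine fixed at position 0. The asymmetric geometry follows the
coverage of the proteomic peptides the benchmark data derive from (average
upstream coverage just under five residues, downstream about eight and a
half). Positions that fall outside the protein are filled with the dummy
residue `X`, which the encoding treats as a 21st symbol — terminal padding
is a real, informative signal for sites near protein ends. Residues
outside the 21-letter alphabet (`B`, `J`, `O`, `U`, `Z`, `*`) are mapped
to `X` with a warning, keeping the encoding alphabet fixed.

Negative sites are, by default, every non-annotated lysine of the
annotated proteins (`build_benchmark(..., negatives = "auto")`). This is
the standard construction for PTM benchmarks when only positive sites are
curated; a precomputed negative list is accepted via
`negatives = "given"`.

### Redundancy filtering

`redundancy_filter()` removes near-duplicate windows: a single greedy pass
in input order drops a window whose identity to any previously retained
window is at or above the threshold (default 40%). Identity is Hamming
identity — exact position-wise matches divided by the window length, with
`X` an ordinary symbol — the only alignment-free reading for ungapped
equal-length windows. Keeping the earlier window on conflict makes the
result deterministic, and re-filtering a filtered set removes nothing. The
threshold and whether comparison crosses class boundaries are
configurable: a strict 40% Hamming cut on 16-mers sharing a central K is
aggressive (every pair already agrees at the center), so the default
should be read as an interpretation, not a calibrated reproduction of any
published set size.

## Feature encoding

Each 16-mer becomes a 687-dimensional vector in four fixed blocks:

| block | dim | content |
|---|---|---|
| A | 21 | 1-gram counts over the 21-symbol alphabet |
| B | 441 | 2-gram counts over the 15 overlapping adjacent pairs |
| C | 15 | residue code (1–21) at each non-center position −6…−1, +1…+9 |
| D | 210 | 14 physicochemical property values at each of those 15 positions |

Residues are coded 1–20 alphabetically by one-letter code, `X` = 21. The
invariant center lysine carries no information and is excluded from blocks
C and D, which is what makes the totals 15 and 15 × 14 = 210. K-gram
features are occurrence counts by default (`kgram_values = "count"`, the
usual k-gram spectrum); a binary presence option exists. Block C is kept
as ordinal integer codes, exactly as the numeric-coding description and
the 15-dimensional total dictate, rather than a one-hot expansion.

The 14 property scales (block D) — hydrophobicity, polarity,
polarizability, solvent accessibility, net charge index of side chains,
molecular weight, pK of the α-amino and α-carboxyl groups, melting point,
optical rotation, entropy of formation, heat capacity, absolute entropy,
and hydrophilicity — ship as an editable TSV
(`system.file("extdata", "property_table.tsv", package = "malsite")`).
The published description of this feature family reads as thirteen
property names yet states fourteen ("solvent, accessibility" is
ambiguous), and no database accession numbers are printed; we therefore
treat the 14th slot as configurable (hydrophilicity by default) and the
whole table as a documented, replaceable input rather than a canonical
constant. `X` contributes 0 for every property by definition.

Features that are constant across a training matrix (both classes pooled)
are removed by a fitted `reduction_mask`; the mask is part of the model
and is refitted inside every cross-validation training fold. How many
features this removes depends on the dataset — with a uniform background
most of the 687 survive; sparser real data lose more 2-gram counts.

## Feature selection: mRMR

From the non-constant features, greedy minimum-Redundancy-Maximum-
Relevance selects 50 (configurable). Step 1 picks the feature with maximal
mutual information with the label; step *t* picks the feature maximizing

* MID (default): `I(f; y) − mean over selected s of I(f; s)`
* MIQ: `I(f; y) / mean over selected s of I(f; s)`

with ties broken toward the lowest feature index. MID is the difference
form of the original mRMR formulation and is the default because the
source protocol does not name its variant; both are recorded in the model.

Mutual information is the plug-in estimate on empirical joint counts (in
nats), computed in C++ for speed. Continuous features must be discretized
first: the default maps values below `mean − σ` to one state, above
`mean + σ` to another and the rest to a middle state (population σ,
`alpha = 1`), mirroring the discretization the classic mRMR program
documents for continuous data; integer-valued columns (blocks A–C) pass
through unchanged. Equal-frequency binning is available as an alternative.

Two caveats the tests make explicit. First, plug-in MI is biased upward
for high-cardinality features at small sample sizes, so selections on a
few dozen samples are noisy — the toy fixtures in the test suite use more
features than the defaults for exactly this reason. Second, whether the
original protocol selected features once on the whole dataset (leaking
test information) or per fold is unstated; the default here is per-fold
selection (`selection_scope = "fold"`), with the leaky whole-dataset mode
available and clearly labeled for comparison.

## Classification

The classifier is a probability-output RBF-kernel SVM (libsvm, via
`e1071`), `gamma = 0.0125`, cost `C = 1`, with sigmoid (Platt) calibration
of the decision values. The published protocol fixes `gamma` but not `C`;
`C = 1` is recorded as the default and `tune_cost()` provides a
cross-validated grid search for users who want to choose it on their own
data. A window is called positive when `Pr(positive) > θ` with `θ = 0.5`;
a probability exactly at the threshold is called negative — a conservative
tie rule, stated here and in the docs. The calibration's internal
cross-validation draws from R's RNG, so a fixed seed makes refits
bit-reproducible; the seed is stored in the model.

**Feature scaling.** After constant-feature removal, every feature is
min-max scaled to [0, 1] (scaler fitted on training data only, stored in
the model). This is a deliberate design choice: the feature blocks differ
in magnitude by two orders (counts 0–16, codes 1–21, property values up to
several hundred), and an RBF width of 0.0125 ≈ 1/50 — the libsvm
convention for unit-scaled features with 50 dimensions — is only
meaningful after scaling. On the default synthetic conditions the unscaled
pipeline's 6-fold AUC collapses to about 0.63 while the scaled pipeline
reaches about 0.82, close to the Bayes ceiling of the planted signal
(0.886, computable in closed form from the generator's parameters).
`mal_pipeline(scale = FALSE)` restores raw features for comparison.

## Evaluation

`run_kfold()` and `run_loo()` refit the *entire* chain — reduction mask,
scaler, mRMR selection, SVM — on every training fold, so no information
leaks from held-out samples. Stratified folds preserve the class ratio
within one sample per fold; fold assignment rotates across classes so that
`k = n` degenerates exactly to the leave-one-out partition. Every repeat
reshuffles folds under a seed derived deterministically from the master
seed.

Per repeat, held-out scores are pooled into a single ROC/AUC (pooling is
stated rather than assumed because averaging per-fold AUCs is the other
common convention; both numbers are emitted). Across repeats the report
carries the mean and standard deviation of the pooled AUC and a
vertically averaged ROC on a fixed 101-point FPR grid. AUC is computed two
mathematically identical ways — trapezoidal integration of the
threshold-sweep curve and the normalized Mann–Whitney rank statistic with
ties counted ½ — and the test suite requires them to agree to 1e−12.
Sensitivity, specificity, accuracy and the Matthews correlation
coefficient come from the confusion counts at θ; a zero denominator yields
`NA` (Sn/Sp) or 0 with an explicit `undefined` annotation (MCC) rather
than an exception.

## Motif analysis

`frequency_matrix()` gives per-position residue frequencies (21 × 16,
columns summing to 1; `X` is a real row — terminal padding is visible in
short-protein data). `two_sample_enrichment()` compares positive and
negative sets per (position, residue) with a Welch two-sample t-test on
the 0/1 occurrence indicators, reporting pairs with `p < 0.05` signed by
the frequency difference. Welch rather than pooled variance is a choice —
the web tools this emulates do not document their variant — and is
implemented in closed form so that zero-variance indicator columns are
handled by a stated convention (equal constants: no report; unequal
constants: reported with p = 0) instead of an error. No multiple-testing
correction is applied by default, matching common two-sample-logo
practice; a `correction` argument forwards to `p.adjust()`.

## The synthetic-data generator

`synthetic_spec()` defines the study conditions the package is validated
under: 458 positive and 3,974 negative 16-mers (the 1:8.7 imbalance of the
published benchmark), uniform background over the 20 amino acids, glycine
planted at positions −3, −1, +2 of positives with probability 0.3, lysine
at +1, +2, +8 of negatives with probability 0.25, and 5% of windows
truncated at a terminus into `X`-padding. The planted enrichments mirror
the positional preferences reported for real malonylation peptides; the
padding fraction and uniform background are this package's own choices of
a simple, realistic null — real proteomes have non-uniform composition,
homology structure and correlated positions, none of which the generator
simulates. Passing tests therefore demonstrate that the pipeline recovers
positional signal of realistic effect size under realistic imbalance; they
do not certify performance on real proteomes.

`generate_proteome()` embeds spec-generated windows in random proteins
with annotated site tables, including deliberately truncated proteins, so
the FASTA → site-table → benchmark → window path is testable end to end:
extraction must reproduce every planted window exactly, padding included.

## Problem sizes and numerical choices

The validation suite and the acceptance script run the full pipeline at
the study size (n = 4,432) for the 6-, 8- and 10-fold protocols with a
small number of repeats (2–3); the full 30-repeat protocol is available
through `cv_plan(repeats = 30)` and the CLI default. Leave-one-out, which
refits the chain once per sample, is run on a stratified subsample of 500
windows preserving the class ratio: a full LOO at n = 4,432 is thousands
of SVM refits. Because cross-validated AUC grows with training-set size,
LOO is compared against k-fold *at the same subsample size* when checking
that the two protocols agree; comparing subsampled LOO against full-size
k-fold would confound protocol with learning-curve effects.

Other conventions: window positions are labeled −6…−1, 0, +1…+9 with
1-based site coordinates in all I/O; encoding is computed once per dataset
inside cross-validation (it is a pure per-window function, so per-fold
re-encoding would be identical); MIQ's denominator is floored at machine
epsilon; all derived seeds stay below 2^31.

## Known limitations

* The property table is a faithful *format* with defensible defaults, not
  a reconstruction of the original 14 scales, whose accessions are not
  published.
* The SVM cost, mRMR variant, selection scope and calibration details of
  the original predictor are unstated; published AUC values
  (LOO 0.8143; 0.8196/0.8167/0.8178 for 6/8/10-fold) should be treated as
  approximate reference points. The synthetic conditions here land in the
  same range (about 0.82–0.84 for k-fold), which is a consistency check,
  not a reproduction.
* Greedy Hamming redundancy filtering is one reading of the published
  "≥40% pairwise identity" rule; threshold, scope and metric are exposed
  as options.
* The t-test on Bernoulli indicators is approximate for rare residues;
  with 336 implicit tests per comparison, uncorrected p < 0.05 reports
  ~5% false positives by construction.
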