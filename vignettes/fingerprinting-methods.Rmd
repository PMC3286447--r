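---
title: "Methods: plasma metabolic fingerprinting with plasmafp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plasma metabolic fingerprinting with plasmafp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmafp)
```

## The problem

Untargeted LC-MS metabolic fingerprinting compares whole intensity patterns
of plasma metabolites between clinical groups. `plasmafp` implements the
complete desk-scale analysis for a three-group design — controls (`C`),
small abdominal aortic aneurysm (`S`, < 5 cm) and large aneurysm (`A`,
> 5 cm) — from an aligned feature table through presence filtering,
univariate statistics, supervised multivariate classification with
validation, and compound annotation. Because no public raw data exist for
this design, the package ships a synthetic cohort generator with known
ground truth; every downstream stage is exercised and tested against that
truth, and real feature tables can be substituted through the same CSV
entry point.

## The data model

A `feature_table` holds aligned features (neutral mass in Da, retention
time in minutes) by samples (class labels `C`, `S`, `A`, `QC` for pooled
quality-control replicates, `P` for prediction-only samples). A cell is
`NA` when the feature was not detected in that sample — missingness means
"not detected", and is never imputed as zero, so that presence filtering
is meaningful.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions:

* 11 samples per modeled class plus 8 prediction-only samples (4 with
  large-aneurysm effects, 4 with small), i.e. 41 samples in total, and 13
  QC replicates from `generate_qc_block()`;
* 600 aligned features, of which 60 carry true multiplicative group
  effects; the default effect panel cycles through percent changes typical
  of the discriminating metabolite classes in this design (a several-fold
  increase for a guanidinosuccinic-acid-like marker of large aneurysm, and
  30–70 % decreases with the small group intermediate for acylcarnitines
  and lysophospholipids), with `percent = (fold − 1) × 100` exactly;
* log-normal intensities: per-feature baselines `N(5, 1)` on the log10
  scale, within-group dispersion `noise_log10_sd = 0.03`;
* Bernoulli detection at `presence_rate = 0.95` per cell;
* QC replicates drawn log-normally around the control baseline with
  per-feature CVs uniform in 5–45 %.

Two generator parameters deserve comment because the design was genuinely
open:

* **Within-group dispersion** (`noise_log10_sd`, default 0.03 ≈ 7 % CV).
  The generator is required to *recover its own configured effect sizes*:
  the realized percent change of every discriminating feature at
  n ≥ 100 per group must sit within ±10 percentage points of the
  configured value. The sampling error of a raw-scale percent change
  scales with the fold itself, so the ±10-point band at a fold of 4.09
  (+309 %) forces a small within-group CV. The default therefore emulates
  a strongly separated, low-dispersion fingerprint rather than the full
  biological variance of a real plasma cohort (often 20–60 % CV); users
  can raise `noise_log10_sd` freely, at the price of weaker recovery
  guarantees. Consequences for interpretation: passing tests demonstrate
  correctness of the pipeline arithmetic and the qualitative study
  structure (class separability, intermediate position of the small-AAA
  group, QC behaviour), not expected classification accuracy on real
  cohorts.
* **Missingness** is missing-completely-at-random per cell. Real
  feature-extraction missingness is abundance-dependent; the generator
  does not model that, which is acceptable because the presence filter
  and half-minimum imputation downstream do not assume any particular
  mechanism.

Determinism: every generator draws from a stream derived from one integer
seed, restoring the caller's RNG state afterwards; equal `(config, seed)`
give bit-identical output.

## Preprocessing

* **Alignment** (`align_peak_lists()`): greedy nearest-centroid
  clustering of pooled peaks in (mass, rt) order, with windows in ppm and
  minutes, intensity-weighted running centroids, and a most-intense-wins
  rule when a sample would contribute two peaks to one cluster. The
  procedure is deterministic because peaks are sorted before clustering.
* **Presence filter** (`presence_filter()`): the primary rule keeps
  features detected in at least `min_count = 10` samples of *any* modeled
  group; the secondary, per-comparison rule requires 10 detections in
  *each* of the two compared groups. In the pipeline the secondary filter
  is applied to the primary-filtered table.
* **Transform**: common logarithm of intensities (`log10_transform()`),
  bringing log-normal intensities to normality; normality per feature can
  be checked with `shapiro_wilk()`.

## Univariate statistics

`compare_groups()` runs Welch's unequal-variance t test per feature on
log10 intensities (missing values excluded pairwise) and reports the
percent change of raw-scale group means — testing on the log scale and
reporting fold-like changes on the raw scale reproduces the reference
arithmetic (e.g. means 40.9 vs 10.0 give +309 %). Significance is read at
raw p ≤ 0.05 with no multiplicity correction, matching the original
workflow; Benjamini–Hochberg q-values are emitted alongside as a clearly
supplementary column. QC reproducibility is summarized per feature as
`100 × sd/mean` of raw QC intensities (n−1 standard deviation, the
standard for small replicate counts).

## PLS-DA

`fit_plsda()` implements NIPALS PLS2 regression of the one-hot class
indicator on the feature matrix:

1. `X` is always mean-centered; unit-variance scaling is optional and off
   by default ("no scaling" in the chemometrics sense retains centering).
2. Per component: iterate `w ∝ X'u`, `t = Xw`, `c ∝ Y't`, `u ∝ Yc` to
   convergence, then deflate both blocks with the loading `p = X't/t't`.
3. Cumulative `R²X`/`R²Y` come from residual sums of squares; scores are
   mutually orthogonal by construction.

Numerical choices: convergence is declared when the relative score change
drops below 1e-10; the iteration cap is 20 000 and reaching it is an
error naming the component. The cap is generous on purpose — each
iteration is only two matrix–vector products, and slow convergence occurs
exactly when the two leading eigenvalues of `X'YY'X` nearly coincide
(e.g. on label-permuted null data), where the extracted direction is
near-arbitrary within the leading eigenspace but predictions are
unaffected. Sign indeterminacy is fixed by making the largest-magnitude
weight entry positive. The one-component weight equals the dominant
eigenvector of `X'YY'X`, which the tests verify against an independent
eigendecomposition.

Projection of new samples uses the standard rotation `W(P'W)⁻¹`;
prediction assigns the class with the largest fitted indicator response.
A `margin` parameter formalizes the reading of a sample "classified
between" two groups: when the two largest responses differ by less than
the margin the sample is `unassigned` (default margin 0 for accuracy
bookkeeping, 0.1 for the pipeline's narrative report).

Missing cells entering PLS-DA are imputed as half the feature's minimum
observed in the *training* samples (`impute_half_min()`): deterministic,
scale-respecting, and applied on the raw scale before the log transform.

## Validation

* **Q²** (`q2_cross_validation()`): `1 − PRESS/SS` accumulated per
  component, with class-stratified venetian-blind folds (default 7) after
  a seeded shuffle; a fold layout that would strip a class from any
  training set is re-drawn (at most 10 times). `Q² ≤ R²Y` on every
  dataset, and label permutation drives the mean Q² to or below zero.
* **Leave-1/3-out** (`leave_third_out_validation()`): each repetition
  excludes a random class-stratified third, refits, and predicts the
  excluded samples by strict argmax; repetitions continue until every
  sample has been excluded at least once (minimum 3). The report carries
  per-repetition accuracies, mean ± sd, coverage counts and a confusion
  tally. The number of repetitions is an emergent property of the
  coverage rule, not a fixed count.

## Annotation

`monoisotopic_mass()` computes neutral and singly-charged masses from
Hill-notation formulas with principal-isotope masses at ≥ 6 decimals;
`[M+H]+` adds the proton mass 1.007276 Da (not a hydrogen atom — the
distinction is 0.5 mDa and visible at 4 decimals). Accurate-mass search
(`search_mass()`) uses a 15 ppm default window against a packaged
~46-entry compound table covering the discriminating metabolite classes
plus decoys — a desk-scale stand-in for the large public databases; the
TSV dialect accepts any user-supplied table. Class confirmation
(`match_fragment_rules()`) encodes the diagnostic fragments:
60.08/85.03 m/z for acylcarnitines, 184.07/104.11/86.1 m/z (any two) for
lysophosphatidylcholines, and a 141.02 Da neutral loss of
phosphoethanolamine for lysophosphatidylethanolamines, each within a
0.02 m/z window.

## The pipeline

`run_pipeline()` chains the seven stages (acquire → primary filter →
3-class model with QC projection and validation → held-out prediction →
per-comparison statistics → 2-class A-vs-C model with projection of all
small-AAA samples → annotation), writing CSV/JSON artifacts and a JSON
manifest with per-stage counts. QC samples are projected but never
fitted; prediction-only samples never influence the filter. On the
default synthetic cohort the pipeline reproduces the qualitative study
findings: QC replicates project next to the control class, both models
validate at 100 % leave-1/3-out accuracy, held-out samples are assigned
to their true classes, and the small-aneurysm samples fall between the
control and large-aneurysm score centroids on the first component.

Problem sizes used throughout the tests and the acceptance script are the
study design itself (600 features, 11 + 11 + 11 modeled samples, 13 QCs,
8 held-out samples), with n = 200 per group only for the generator
recovery checks — sizes chosen to mirror the design while keeping a full
run in seconds.

## Known limitations

* The generator omits batch drift, abundance-dependent missingness,
  isotope patterns and chromatographic artifacts; QC noise is the only
  analytical-variance component.
* No normalization or batch correction is applied anywhere (none is part
  of the emulated workflow).
* Annotation is positive-mode `[M+H]+` only, and the packaged database is
  deliberately small; real studies should supply their own table.
* Significance is reported at uncorrected p ≤ 0.05 by design; the
  q-value column should be preferred for any modern reanalysis.
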