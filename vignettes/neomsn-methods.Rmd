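---
title: "Morphometric similarity networks for the neonatal brain: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric similarity networks for the neonatal brain: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A morphometric similarity network (MSN) is an individual, per-subject brain
network. Each region of interest (ROI) of a parcellation is described by a
vector of regional metrics derived from several MRI contrasts — here up to
twelve: ROI volume and the myelin-sensitive T1w/T2w signal ratio
(structural), fractional anisotropy, mean/axial/radial diffusivity and mean
kurtosis (diffusion kurtosis model), and the intracellular and isotropic
volume fractions plus three orientation dispersion indices (Bingham-NODDI).
Within a subject, each metric is z-scored across the ROIs, and the edge
between ROIs $i$ and $j$ is the Pearson correlation

$$ w_{ij} = \mathrm{cor}\big(z_i,\, z_j\big), $$

where $z_i$ is ROI $i$'s z-scored metric vector. The network is symmetric
with unit diagonal; its strict upper triangle, flattened row-major, is the
subject's edge feature vector ($\binom{81}{2} = 3240$ features for the
81-region parcellation). The parcellation is the dHCP neonatal 87-label
scheme with six labels excluded at the atlas level (background, unlabelled
area, CSF, both lateral ventricles and the corpus callosum); the shipped
atlas file uses a dHCP-*compatible* ordering, with hemisphere, tissue class
and homotopic partner recorded per ROI.

Two cross-validated models consume the edge vectors:

* **Brain age**: elastic-net linear regression of postmenstrual age (PMA)
  at scan, with sex and PMA at birth appended as (penalized) covariates.
  Leave-one-out cross-validation (LOOCV) is the primary scheme; inside
  every training fold the penalty mixing and strength are re-tuned with a
  3-fold inner loop stratified in percentiles of the age range.
* **Term/preterm classification**: linear support-vector machine with
  recursive feature elimination (SVM-RFE); age at scan, sex and absolute
  motion are appended. Within each training fold an outer 3-fold loop
  selects the SVM cost and an inner 4-fold loop selects the retained
  feature count; folds are stratified by group.

Summary measures are the mean absolute error (MAE, with the SD of the
per-subject absolute errors) and Pearson's r for regression, and the
fraction of correctly classified held-out subjects for classification.
Per-fold selected-feature masks are recorded so that *stable edges* —
selected in at least 99% of folds — can be extracted and signed by their
correlation with the target across subjects.

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| elastic-net mixing grid | 0.1, 0.5, 0.7, 0.9, 0.95, 1 | conventional glmnet-style grid |
| penalty strength grid | 20 log-spaced in $[10^{-3}, 10]$ | spans near-OLS to heavy shrinkage |
| inner folds (regression) | 3, quartile-stratified | small-cohort compromise |
| SVM cost grid | 0.01, 0.1, 1, 10 | standard linear-SVM range |
| RFE retained-feature grid | 25–800 | covers sparse to dense edge sets |
| RFE elimination step | 10% per iteration | standard SVM-RFE practice |
| stability threshold | 0.99 | the strict "99% of folds" filter |
| permutation count | 99 desk-scale, 1000 full | add-one p floor 0.01 / 0.001 |

All grids are exposed through `regression_config()` /
`classification_config()`; hyperparameter ties resolve to the smallest
penalty strength, smallest cost and fewest RFE features, which is
deterministic and parsimony-first.

## Numerical and design choices

* **Z-score divisor.** Population SD (divisor $n$). Pearson correlation is
  affine-invariant, so the choice cannot affect MSN values; it is fixed
  only so intermediate files reproduce bit-for-bit.
* **Subsets of three metrics** are the smallest the elimination scheme
  evaluates; correlations over three points are coarse, and subsets of
  fewer than three are rejected outright. The two-metric structural-only
  model is therefore evaluated as a concatenated-regional-metrics model
  and flagged as a fallback.
* **In-fold standardization.** Features are standardized inside each
  training fold with training statistics only; constant columns get unit
  scale. The same applies within the inner tuning loops. A duplication
  probe test verifies that adding a held-out subject to training changes
  its prediction.
* **Order invariance.** Fold assignment derives from a canonical ordering
  of the training subjects (target value, then subject id) and a seed
  derived from the configuration seed; permutation draws are made in
  subject-id order. Cross-validated predictions and permutation p-values
  are therefore invariant to the order in which subjects are supplied.
* **Permutation p-values** use the add-one convention,
  $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$, which cannot
  return zero.
* **Backward elimination** removes, at each level, the metric whose
  removal degrades the score least; ties remove the metric later in
  canonical order. From 12 metrics down to 3 this makes exactly
  $1 + \sum_{k=4}^{12} k = 73$ evaluations. All 73 subsets share one
  master seed, so the path is reproducible bit-for-bit.
* **Hemisphere interchangeability.** The observed statistic is the count
  of stable right-hemisphere edges minus stable left-hemisphere edges.
  Under the null each homotopic pair is swapped independently with
  probability 1/2, identically across subjects (preserving region identity
  under the null), and the *entire* analysis is re-run. The statistic is
  antisymmetric under a global left/right relabelling.

## The synthetic cohort generator

The generator exists so that every stage of the pipeline is testable
without access to the restricted cohort. Its defaults mirror the study
conditions: 46 term and 59 preterm infants, birth ages 37–42 and
23.42–32.0 weeks, scan ages in [38, 44.56] weeks with a positive
scan-age–birth-age correlation and a negative scan-age–sex correlation
(term-born and female infants scanned later), and a higher absolute-motion
mean in the preterm group.

Regional metrics are generated as

$$ x_{r m} = a_{c(r) m}\,\big(1 + s\,\Delta t\big)
  + d_{r m}\,\big(1 - c\,\Delta t\big) + \varepsilon_{r m}, $$

where $a_{c m}$ is the tissue-class archetype profile (classes: cortical
grey matter, white matter, subcortical grey matter, brainstem,
cerebellum), $\Delta t$ is scan age minus 40 weeks, $s$ and $c$ are the
class-contrast growth and deviation-shrink rates scaled by `age_effect`,
$d_{r m}$ is a region-specific deviation *shared between homotopic
partners* (mirror symmetry, making the swap test's null exact by
construction), and $\varepsilon$ is i.i.d. noise with per-metric dispersion
scaled by `noise_sd`. Preterm subjects receive an additional shift on a
fronto-temporal/subcortical subnetwork (`group_effect`), and
`lateralization` multiplies the age terms on right-hemisphere ROIs.
Values are clipped into their physical domains (positive volumes and
diffusivities, unit-interval fractions), with clip counts recorded.

This construction reproduces the qualitative structure the analysis
relies on: a block-structured cohort-average MSN (positive similarity
within grey matter and within white matter, negative between them),
within-tissue convergence and grey–white divergence with increasing scan
age, a preterm group contrast, and the confound correlations. It does
*not* emulate spatial autocorrelation between neighbouring ROIs,
metric-specific noise covariance, scanner/session effects, or exact
printed cohort statistics beyond ranges and sign structure — so passing
tests demonstrate correctness of the machinery and calibration of the
inference, not expected real-data effect sizes.

`generate_null_cohort()` zeroes the age, group and lateralization effects
*and* the confound structure (motion gap, scan-age correlations): the
classifier receives motion as a covariate, so a motion gap would leave the
target predictable from metadata and the null would not be a null.

## Problem sizes used in tests

Simulation-based tests and the acceptance script run on reduced problem
sizes chosen as a realistic desk-scale design: a 15- or 21-region
simulation atlas with the same tissue classes and pairing structure as the
full 81-region atlas, cohorts of 30–40 subjects, single-repeat 5-fold or
LOOCV schemes, a lasso-leaning reduced tuning grid, and 99 permutations
(p floor 0.01). Calibration checks use 20 independent repeats and compare
the empirical p-value distribution to uniform with a Kolmogorov–Smirnov
statistic against the 5% critical value (0.294 at $n = 20$). Parameter
recovery uses the strong-planted-signal regime (metric noise SD 0.3 in
dispersion units): at that signal-to-noise the cross-validated MAE beats
the mean-predictor and the confounds-only baseline and decreases
monotonically in the planted effect size (one inversion tolerated as
simulation noise). "Chance level" for the null classifier is the 99%
binomial band around the class prior.

## Known limitations

* The shipped atlas is dHCP-*compatible*: correct counts, classes and
  pairing, but not guaranteed identical to any specific published ROI
  ordering; analyses of real data should supply their own atlas file.
* Pearson similarity over small metric subsets is coarse; results from
  3-metric MSNs should be interpreted with care.
* The classifier's nested RFE is expensive at full grid settings; the
  defaults mirror standard practice, and reduced grids are recommended for
  exploration.
* Stability selection ("99% of folds") is the only multiplicity control,
  by design; no edge-wise multiple-testing correction is applied.
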