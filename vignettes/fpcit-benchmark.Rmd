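---
title: "Benchmarking FP-CIT classifiers on synthetic cohorts: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking FP-CIT classifiers on synthetic cohorts: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fpcitbench` compares two families of binary classifiers of (I123)FP-CIT
striatal uptake — normative semi-quantification cut-offs and SVM pipelines —
under a shared, leakage-free cross-validation harness. Because real FP-CIT
databases are not redistributable, the package is driven by a synthetic
generator whose statistical structure reproduces the features those
classifiers rely on. This vignette documents the generative model, the
classifiers' exact conventions, the numerical choices, and what conclusions
the synthetic setting does and does not support.

## The generative model

A subject of class $y \in \{\text{normal}, \text{abnormal}\}$ has

* age $a \sim N(\mu_{a,y}, \sigma_{a,y}^2)$, truncated at 1 year;
* sex $\sim$ Bernoulli with class-specific male proportions (generated for
  demographic fidelity only; no classifier uses it);
* noise-free SBR in region $r$ (putamen or caudate, either side)
  $$\mu_r(a) = \beta_{0,r} + \beta_1 a,$$
  with $\beta_1 \le 0$ capturing the age-related decline of striatal
  dopamine-transporter density;
* for abnormal subjects, a single laterality factor
  $q \sim N(0, \sigma_q^2)$ scales the fractional drops applied to both
  regions: the left side loses $d_r (1+q)$ and the right $d_r (1-q)$ of
  its normal mean (clamped to $[0, 0.95]$). Sharing $q$ between putamen and
  caudate makes disease consistently lateralised within a subject, and
  $d_\text{putamen} \ge d_\text{caudate}$ enforces putamen-dominant
  degeneration;
* observed SBRs add independent Gaussian noise with region-specific SD and
  are truncated to stay positive (at $10^{-6}$).

The noise SD is a *between-subject population* spread (biology plus
measurement), not a test–retest error, which is why its defaults are several
tenths of an SBR unit.

### Defaults and presets

Intercepts default to 3.0 (putamen) and 3.5 (caudate) SBR units at age zero
with slope $-0.005$/year, giving normal putamen means near 2.7 at age 60 —
representative of screened control populations. The disease-effect and noise
magnitudes are **package defaults, not measured values**; they were fixed
once, by analysis of the implied class separation, so that the two presets
bracket the difficulty ordering seen between screened research databases and
heterogeneous clinical archives:

| parameter | `"research"` | `"clinical"` |
|---|---|---|
| default counts (normal/abnormal) | 209 / 448 | 113 / 191 |
| age mean (SD), normal | 60.8 (11.3) | 68.7 (12.4) |
| age mean (SD), abnormal | 61.6 (9.8) | 68.7 (13.3) |
| putamen / caudate drop | 0.55 / 0.35 | 0.45 / 0.25 |
| asymmetry SD $\sigma_q$ | 0.05 | 0.10 |
| SBR noise SD (both regions) | 0.5 | 1.0 |

With four informative regions these choices put the generative Bayes accuracy
(see below) near 0.99 for the research preset and near 0.85 for the clinical
one, so "clinical" is strictly harder for every classifier — the qualitative
ordering the benchmark is designed to reproduce. `estimate_bayes_rate()`
computes that ceiling by Monte-Carlo: it draws subjects from the model and
applies the exact Bayes rule, with the laterality factor integrated out by
21-node Gauss–Hermite quadrature. The positivity truncation is ignored in the
densities; at the default parameters its probability mass is negligible.

### Phantom volumes

`generate_volume()` builds a cubic template-space grid (default $64^3$,
2 mm voxels): everything at background level $B$, each striatal ROI at
$B(1+\mathrm{SBR}_r)$, plus Gaussian voxel noise of SD
$\texttt{noise\_sd}\cdot B$ truncated at zero. The ROI layout — ellipsoidal
putamen/caudate pairs, a cuboid occipital reference, and a boxy
(exponent-4 superellipsoid) loose striatal mask — is mirror-symmetric about
the central sagittal plane, validated at construction (disjointness,
containment, symmetry), and scales with the grid size. Registration is
assumed perfect: all subjects share the template masks. No SPECT physics
(collimator blur, scatter, attenuation, partial-volume effects) is simulated;
the phantoms exist so that the image-domain pipelines (occipital scaling,
worst-side flipping, loose masking, per-fold PCA) can be exercised and
round-tripped exactly, not to mimic camera data.

## Semi-quantification conventions

The 18 built-in rules combine a comparison set, regions, and a cut-off
estimator; a subject is abnormal as soon as *any* considered value falls
strictly below its limit. Conventions the literature leaves open were fixed
as follows:

* **Sample SD** ($n-1$ denominator) in mean − kSD limits.
* **"Standard error" of the regression band** is the *residual* standard
  error $\sqrt{\mathrm{RSS}/(n-2)}$, matching how clinical normal bands are
  drawn around a regression line, not the (much narrower) standard error of
  the predicted mean. The regression is fitted on **all** normal training
  records, never the age-matched subset — the line itself models age.
* **Boundary equality**: an SBR exactly on its cut-off is *within* normal
  limits.
* **Age matching** uses a ±5-year window inclusive at both bounds. If fewer
  than `min_support = 5` comparators (per class, for the two-class ROC
  variants) are found, the window widens symmetrically in 1-year steps until
  support is reached, rather than failing mid-experiment.
* **ROC cut-offs** maximise training accuracy of "abnormal iff value < c"
  over midpoints of consecutive distinct pooled values plus one sentinel
  below the minimum and one above the maximum; ties go to the smallest
  threshold, which favours specificity. Each discriminant (lowest putamen,
  lowest caudate) gets its own independently fitted threshold.
* Of the four ROC variants, `SQ15`/`SQ16` use the whole two-class training
  set and `SQ17`/`SQ18` the per-test-subject age window, following the
  methods' definition table in the source material (whose results tables
  label the pair the other way around).

These conventions yield two provable monotonicities that the acceptance
suite checks exhaustively: tightening $k$ ($1 \to 1.5 \to 2$) can only lose
abnormal calls (sensitivity non-increasing, specificity non-decreasing), and
adding caudate limits to fixed putamen limits can only add abnormal calls.

## SVM pipelines

All 13 pipelines use libSVM (via `e1071`) as the soft-margin classifier:

* **Features**: the four SBRs; or occipitally scaled, worst-side-flipped,
  loose-masked voxels; or their first 3/5/10/15/20 principal components.
  Age is appended to every family and standardized like any feature.
* **Flipping before learning**: volumes are mirrored so the most diseased
  (lowest-uptake) striatum is always on the left; a tie leaves the volume
  unchanged. Flipping, scaling and masking are per-subject, label-free
  operations, so they are applied once per cohort; everything fitted —
  standardizer, PCA, hyperparameters, SVM — uses training rows only.
* **PCA** is centred (not scaled) and fitted inside each training fold;
  projected coefficients are then standardized. Standardizing after
  projection (rather than standardizing voxels before it) was chosen because
  it treats the coefficient scales exactly as the SBR features are treated; a
  different order would change only the relative weighting of components.
  With many more voxels than subjects the decomposition runs through the
  Gram matrix, which is exact and much faster.
* **Hyperparameters**: coarse grid $C \in 2^{-3}..2^8$,
  $\gamma \in 2^{-8}..2^3$ (step ×2; $\gamma$ ignored for linear kernels),
  selected by mean F-score of the abnormal class over a single pass of
  stratified 10-fold inner cross-validation; ties break to the smallest $C$,
  then the smallest $\gamma$, for determinism. The feature transform has no
  hyperparameters, so it is fitted once per inner fold and shared across the
  grid — a pure speed-up with identical results.
* Voxel features admit only the linear kernel (with thousands of inputs a
  kernel adds nothing and invites overfitting); `ml_spec()` rejects the
  combination.

## Evaluation harness

`run_experiment()` runs repeated (default 10×), stratified, nested 10-fold
cross-validation. Stratification assigns each fold the floor or ceiling of
$n_c/k$ members of each class, randomising which folds take remainders. All
methods see identical fold assignments within a repetition, so method
contrasts are paired. Abnormal is the positive class throughout. Per-repeat
fold seeds and per-cell grid-search seeds derive from the master seed by a
fixed counter scheme, making the whole experiment a pure function of
(cohort, configuration, seed) — reports re-run byte-identically. Methods
failing on a fold would abort loudly rather than silently dropping cells; the
window-widening rule above is what prevents that for sparse age strata.

## Problem sizes and what the tests show

The heavy evaluations use sizes chosen to exercise the full pipeline while
keeping the suite quick to run: cohorts of ~300 subjects (research preset
shaped 95/205 like 209/448; clinical at its native 113/191), phantom grids of
$48^3$ ($32^3$ in unit tests; the package default is $64^3$), 10 outer folds
× 3 repetitions, and 5 generator seeds per preset. At those sizes the
acceptance suite verifies that the 3-PC linear SVM reaches the Monte-Carlo
Bayes ceiling within 0.05 and matches or beats the best semi-quantification
rule (within 0.02), and that every method scores strictly lower on the
clinical preset than on the research one.

Passing these tests shows the *machinery* is correct and the *qualitative*
orderings are reproduced under a known generative model. It does **not**
show that the absolute accuracies transfer to real scans: the synthetic
cohorts have Gaussian class-conditional SBRs, perfectly registered phantoms,
no scanner effects, no diagnostic label noise, and a disease effect that is
linear in the normal mean. Real clinical archives violate all of these, which
is precisely why their classification accuracies are lower and noisier.

## Known limitations

* No SPECT physics or registration error in the phantoms; voxel pipelines see
  idealised images.
* The Bayes-rate estimator ignores SBR truncation at zero; at extreme noise
  levels (SD comparable to the mean) it becomes an approximation.
* Statistical significance testing between methods is deliberately out of
  scope: repeated cross-validation re-uses data, so fold-level SDs are
  descriptive, not inferential.
* Sex is generated but unused, mirroring the methods under study.
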