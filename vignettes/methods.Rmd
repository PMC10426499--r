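---
title: "Methods: translation-robust radiomics for hypertrophic cardiac phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: translation-robust radiomics for hypertrophic cardiac phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Cardiac amyloidosis (CA) and aortic stenosis (AS) both produce a hypertrophic
left-ventricular (LV) phenotype, but their prognoses and treatments differ,
and the two conditions frequently coexist in elderly patients referred for
valve replacement. Contrast cardiac CT is acquired routinely in that workup,
so a classifier that separates the two phenotypes from the LV-wall radiomic
signature of a single arterial-phase scan would add diagnostic value at no
acquisition cost. `radiostab` implements such a pipeline end to end, with a
deliberate emphasis on *feature robustness*: radiomic features are screened by
how they behave under small and large rigid translations of the ROI before
any supervised learning happens.

Because no patient data ship with the package, every stage is developed and
tested against a synthetic phantom cohort whose ground truth is known by
construction.

## Pipeline

1. **Phantom** (`generate_cohort()`): hollow-shell ellipsoid ROIs ("LV wall")
   over textured volumes; two classes differing in texture statistics.
2. **Preprocessing** (`denoise()`, `resample()`): 3×3×3-voxel Gaussian
   (σ = 0.5 voxels) denoising, then B-spline resampling to an isotropic 2 mm
   grid. The mask is resampled with nearest neighbour so it stays binary.
3. **Extraction** (`extract_features()`): 107 features — 14 shape-size (SS),
   18 first-order (FOS), 75 textural (24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM,
   5 NGTDM) — with fixed-bin-width discretization at 0.5 HU.
4. **Robustness screen** (`robustness_screen()`): per non-shape feature,
   intraclass correlation between original and translated-ROI values across
   subjects; minimal (±0.5% of the ROI bounding box, x and y) translations
   probe *stability* (mean ICC > 0.75), maximal (±30%) translations probe
   *discrimination* (mean ICC < 0.5). Robust = both. SS features are
   invariant to rigid mask translation and bypass the screen.
5. **Redundancy filter** (`correlation_filter()`): absolute Spearman
   correlation threshold ∈ {0.80, 0.85, 0.90, 0.95, 1}; of an offending pair
   the member with the lower mean absolute correlation to the rest is kept.
6. **Relevance selection**: rank-sum p-value, LASSO, ssLASSO (p-value →
   LASSO), PCA at 95% cumulative variance, ssPCA, and sequential forward
   selection (SFS).
7. **Augmentation** (`smote_augment()`): per-class SMOTE with Q = 5 that
   exactly doubles a balanced training fold (29 → 58).
8. **Evaluation** (`loo_run()`): leave-one-out CV over the
   threshold × selector × classifier grid (kNN, SVM, decision tree, logistic
   regression, gradient boosting), pooled accuracy / sensitivity /
   specificity with CA as the positive class.
9. **Explanation** (`shap_explain()`, `pc_class_attribution()`): exact
   Shapley attributions of the final model's decision score over its PC
   inputs, and attribution of each PC to a feature class by the half-max
   squared-loading rule.

## The phantom: what it emulates, and what it does not

Each subject is a 72×72×92 voxel volume at 1 mm spacing containing an
ellipsoid shell (outer semi-axes 20×20×26 mm, inner 13×13×19 mm, i.e. a
~7 mm wall) whose interior intensities are a stationary Gaussian random
field: white noise filtered with an isotropic Gaussian kernel whose standard
deviation is the class's *texture correlation length*, renormalised to the
class SD and shifted to the class mean. Defaults:

| parameter | CA (label 1) | AS (label 0) | rationale |
|---|---|---|---|
| mean (HU) | 140 | 140 | contrast-enhanced myocardium; equal, so intensity does not separate classes |
| SD (HU) | 25 | 25 | moderate heterogeneity |
| correlation length (mm) | 5.0 | 2.5 | coarser texture for CA; texture alone drives the separation |
| subjects per class | 15 | 15 | balanced 30-subject cohort |

Outside the shell the volume is background noise at 40 ± 10 HU. Smoothing a
unit-variance white field and renormalising by the *empirical global* SD
makes the inside-ROI SD approximately (not exactly) the configured value;
within-ROI SD is biased slightly low when the correlation length is
comparable to the wall thickness, because deviations are measured about the
local shell mean. The mask bounding box always keeps a ≥ 35% margin to the
volume boundary so that ±30% translations never clip.

Two switches matter for experiments:

* `fill = "full"` draws the class's stationary field over the *whole* volume.
  This is the right setting for translation-robustness experiments: a
  translated ROI then samples statistically identical texture, which is the
  premise of the stability criterion. With the default `fill = "shell"`,
  translated ROIs sample background and every intensity feature changes
  grossly.
* per-class `inner_scale` changes wall thickness (a shape difference). It is
  off (1) by default so that texture, not shape, carries the class signal —
  matching the setting the pipeline is designed to probe, where textural
  features dominate the explanation.

The phantom does **not** emulate cardiac anatomy, contrast dynamics, partial
volume beyond trivial resampling effects, scanner-specific noise spectra, or
inter-operator segmentation variability. A green end-to-end test therefore
establishes that the pipeline recovers a known texture signal without
leakage — not that any particular clinical accuracy is attainable.

## Feature definitions

The 107-feature set follows the IBSI-style definitions used by the standard
3D extractors (fixed-bin-width discretization; GLCM/GLRLM accumulated over
the 13 unique 3D directions at distance 1 with per-direction feature values
averaged; GLSZM zones by 26-connectivity; GLDM at distance 1 with dependence
α = 0; NGTDM over the 26-neighbourhood). Deviations a reader should know
about:

* **Mesh quantities are voxel-based approximations.** Mesh volume is taken
  as the voxel volume, and surface area as the exposed-voxel-face area. The
  face-count estimator overestimates the area of smooth surfaces (hence
  underestimates sphericity); both are consistent across subjects, which is
  what the pipeline needs. Principal-axis lengths use the eigenvalues of the
  voxel-coordinate covariance; maximum 2D/3D diameters use surface voxels.
* **GLDM dependence counts include the centre voxel** (sizes start at 1),
  avoiding a zero division in the small-dependence emphases.
* **Degenerate ROIs** (e.g. constant intensity) yield 0 for otherwise
  undefined feature values rather than NaN, so downstream screening sees a
  finite, flaggable value.

## Numerical and design choices where the design was open

* **Translations are applied after preprocessing** (on the 2 mm grid), so
  original and translated extractions share one geometry; the commanded
  shift `fraction × bounding-box length` is rounded to the nearest whole
  voxel with a floor of 1 voxel, so the minimal entity is never a no-op and
  no interpolator-dependent sub-voxel re-rasterization is involved. At a
  2 mm grid a "minimal" translation is therefore one 2 mm step — coarser in
  relative terms than on a fine clinical grid, which makes the stability
  criterion *harder* at desk scale, not easier.
* **ICC form**: two-way, absolute-agreement, single-measure — ICC(A,1).
  Stability must mean agreement, not mere consistency, so systematic offsets
  introduced by a translation must lower the coefficient. Computed from the
  closed-form mean squares; values clipped to [−1, 1]; the
  both-vectors-constant case is defined as 1 when identical and flagged
  degenerate otherwise.
* **Redundancy filter order**: the pairwise keep rule does not fix a global
  order, so the filter greedily resolves the currently highest-correlated
  offending pair and recomputes; ties break lexicographically. This makes
  the result deterministic and lets a brute-force oracle replay it exactly.
  The "mean correlation with the other n−2 features" is taken over absolute
  values.
* **Selector internals**: the rank-sum stage uses α = 0.05; LASSO's λ comes
  from a deterministic stratified internal CV on the training fold
  (`lambda.min`); SFS scores candidate sets by internal CV accuracy of the
  downstream classifier and stops when the best improvement falls below
  0.02 (the literal "until the improvement exceeds the threshold" reading
  would never stop); the first SFS feature is always accepted.
* **SMOTE interpretation**: "duplicate then SMOTE, per class" is implemented
  as its net effect — exactly n_c synthetics per class, one per original
  sample, interpolated toward one of its Q = 5 nearest same-class
  neighbours — which pins the stated 29 → 58 contract without depending on
  whether duplicated rows may be chosen as neighbours. Neighbour metric:
  Euclidean in the (z-scored, selected) training space. Folds with a
  singleton class (only possible in ≤ 5-subject smoke cohorts) skip
  augmentation instead of failing.
* **Leakage discipline**: per fold, z-scoring, the redundancy filter, the
  selector, SMOTE and the classifier are all fitted strictly on training
  rows; SMOTE seeds derive from the master seed and fold index, never from
  data, so corrupting the held-out subject leaves every fitted component
  bit-identical (this is asserted in the tests).
* **Pooled metrics**: LOO performance is reported from the pooled confusion
  matrix over folds (fold-averaged accuracy is identical for LOO; pooled
  sensitivity/specificity are well-defined, per-fold ones are not).
  Undefined ratios are reported missing, never as 0.
* **Classifiers** are implemented in-package (no SVM/tree/boosting library
  is available in the target environment): RBF-kernel soft-margin SVM
  trained by a deterministic SMO (C = 1, γ = 1/(d·mean variance)); kNN with
  k = 5 and deterministic tie-breaks; CART with Gini impurity, depth ≤ 3;
  logistic regression via IRLS; gradient boosting with logistic loss,
  depth-2 regression trees, 100 rounds, learning rate 0.1. Every
  hyperparameter is exposed through `run_config()`.
* **Shapley values are exact**, not sampled: the explained space has ≤ ~12
  PCs, so all 2^k coalitions are enumerated and absent inputs are
  marginalised over a background set (the SMOTE-augmented training scores,
  evenly subsampled to ≤ 32 rows). Additivity
  `base + Σφ = decision score` therefore holds to numerical precision, and
  positive attributions push toward the CA class.
* **PC class attribution**: per component, squared loadings above half the
  component's maximum squared loading are summed by feature class
  (shape-size / first-order / textural); the half-max rule always keeps at
  least the maximum itself.

## What the tests establish

The non-acceptance suite checks each operation against independent oracles
(closed-form Gaussian weights, analytic ellipsoid volumes, an ANOVA-based
ICC, a brute-force redundancy filter, linear-model Shapley identities) and
the spec-level invariants (determinism, subset/idempotence/monotonicity
properties, leakage guards). The acceptance suite runs the full-scale
stated world: the 107/14/18/75 extraction contract, the 29 → 58 SMOTE
contract, oracle agreement of the redundancy filter, ICC correctness, the
robustness screen's behaviour on injected noise versus stationary texture,
end-to-end recovery (SVM/PCA/0.95 leave-one-out accuracy ≥ 0.85 across 5
seeds, with label-permuted controls at chance), and bit-identity of fitted
transforms under held-out corruption.

One deliberate weakening relative to the idealised selector-size ordering:
on desk-scale synthetic data the SFS stopping rule (0.02) terminates after
very few additions, so SFS is not asserted to retain more features than
LASSO; the asserted ordering is p-value ≥ LASSO ≥ ssLASSO with PCA counts
small and stable.

## Known limitations

* Feature values are IBSI-*style* but not bit-compatible with any specific
  extractor (mesh approximations, gray-level handling of empty bins).
* The SMO solver targets n ≤ a few hundred training samples — adequate for
  the augmented folds here, not for large cohorts.
* Only x/y translations are implemented; rotations, erosions and contour
  randomization are out of scope by design.
* The phantom's texture knob (Gaussian correlation length) is a one-
  parameter family; real myocardial texture differences are richer.
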