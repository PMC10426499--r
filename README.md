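# radiostab

Translation-robustness-screened radiomics for differentiating hypertrophic
cardiac phenotypes — cardiac amyloidosis (CA) versus aortic stenosis (AS) —
from contrast cardiac CT volumes with left-ventricular wall masks.

Both diseases thicken the LV wall, but for different reasons (extracellular
amyloid deposition versus pressure-overload hypertrophy), and their
management differs sharply. `radiostab` implements a complete, testable
pipeline that probes whether the LV-wall *texture* signature on a routine
arterial-phase CT separates the two phenotypes:

1. **Synthetic phantoms** — hollow-shell ellipsoid ROIs (an LV-wall
   stand-in) over Gaussian random fields with class-specific texture
   correlation lengths, so the whole pipeline runs and is tested with no
   patient data;
2. **Preprocessing** — 3×3×3 Gaussian denoising (σ = 0.5 voxels), B-spline
   resampling to an isotropic 2 mm grid;
3. **107 radiomic features** — 14 shape-size, 18 first-order, 75 textural
   (GLCM/GLRLM/GLSZM/GLDM/NGTDM), fixed 0.5 HU bin width, IBSI-style
   definitions;
4. **Robustness screening** — for each non-shape feature, the intraclass
   correlation coefficient ICC(A,1) between original-ROI and translated-ROI
   values across subjects; a feature is *stable* if mean ICC > 0.75 under
   minimal translations (±0.5% of the ROI bounding box along x/y) and
   *discriminative* if mean ICC < 0.5 under maximal translations (±30%);
   robust = both;
5. **Redundancy filtering** — absolute Spearman correlation thresholds
   {0.80, 0.85, 0.90, 0.95, 1}, keeping of each offending pair the member
   with the lower mean absolute correlation to the rest;
6. **Six relevance selectors** — rank-sum p-value, LASSO, ssLASSO, PCA
   (95% cumulative variance), ssPCA, sequential forward selection;
7. **SMOTE augmentation** — per-class nearest-neighbour interpolation
   (Q = 5) that exactly doubles a training fold (29 → 58);
8. **Leave-one-out evaluation** — a (threshold × selector × classifier)
   grid over kNN, SVM, decision tree, logistic regression and gradient
   boosting, with every fitted component confined to the training fold;
9. **Explanation** — exact Shapley attributions of the final model over its
   principal components, and attribution of each PC to a feature class via
   the half-max squared-loading rule.

See `vignettes/methods.Rmd` for the model assumptions, parameter choices and
limitations.

## Worked example

```r
library(radiostab)

# 30-subject balanced phantom cohort; classes differ only in texture scale
coh <- preprocess_cohort(generate_cohort(phantom_config(seed = 1)))
tab <- build_feature_table(coh)
print(tab)
#> <feature_table> 30 subjects x 107 features (first-order: 18, shape-size: 14, textural: 75)
#>   labels: 15 positive (CA) / 15 negative (AS)

# leave-one-out evaluation of the reference cell: SVM, PCA, threshold 0.95
gr <- loo_run(tab, run_config(thresholds = 0.95, selectors = "PCA",
                              classifiers = "SVM", seed = 1))
print(gr)
#> <grid_result> 1 cell(s), 30 LOO fold(s)
#>  threshold selector classifier accuracy sensitivity specificity n_failed_folds
#>       0.95      PCA        SVM        1           1           1              0
print(gr$counts)
#>      threshold selector   mean_n      sd_n
#> mean      0.95      PCA 6.033333 0.1825742

# final model on the whole cohort + explanation
fin <- fit_final(tab, 0.95, "PCA", "SVM", run_config(seed = 1))
er <- explain_report(fin)
head(er$attribution)
#>   pc shape-size first-order  textural    dominant
#> 1  1          0   0.2049910 0.5835493    textural
#> 2  2          0   0.0000000 0.6452388    textural
#> 3  3          0   0.4990957 0.0000000 first-order
#> 4  4          0   0.3367112 0.1131996 first-order
#> 5  5          0   0.2741102 0.3208183    textural
#> 6  6          0   0.0000000 0.6684361    textural
round(sort(er$shap$mean_abs, decreasing = TRUE), 3)
#>   PC1   PC2   PC4   PC3   PC5   PC6
#> 0.844 0.233 0.055 0.051 0.050 0.011
```

The LOO accuracy of 1.0 says the pipeline recovers the planted textural
separation without leakage (label-permuted controls sit at chance — see
`tests/testthat/test-acceptance.R`); the counts table reports the PCA
component count per fold (mean ± SD), and the attribution table shows the
per-PC squared-loading sums by feature class — on these phantoms the leading
components are textural-dominant, as expected when texture alone carries the
class signal. The first component carries most of the decision
(mean |SHAP| 0.844) and is textural-dominant; the shape-size sums are zero
because all phantom subjects share the same shell geometry by default.

## Command line

A thin CLI wrapping the same functions ships in `inst/cli/radiostab.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/radiostab.R", package="radiostab"))')" \
    phantom --config cfg.yaml --out cohort/
```

Subcommands: `phantom`, `preprocess`, `extract`, `robustness`, `filter`,
`evaluate`. Volumes are exchanged as text-encoded NRRD plus a `labels.csv`;
feature tables as CSV with a JSON feature-class sidecar.
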