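Package: radiostab
Title: Robust Radiomics Pipeline for Differentiating Hypertrophic Cardiac Phenotypes
Version: 0.1.0
Authors@R: person("radiostab", "developers", email = "radiostab@example.org", role = c("aut", "cre"))
Description: A translation-robustness-screened radiomics pipeline for binary
    classification of hypertrophic cardiac phenotypes (cardiac amyloidosis
    versus aortic stenosis) from contrast CT volumes with left-ventricular
    wall masks. Provides a synthetic 3D phantom generator (hollow-shell ROIs
    over textured Gaussian random fields), Gaussian denoising and B-spline
    resampling, an IBSI-style extractor for 107 radiomic features
    (shape-size, first-order, GLCM/GLRLM/GLSZM/GLDM/NGTDM textures),
    intraclass-correlation screening of feature stability and discrimination
    under minimal and maximal ROI translations, Spearman-correlation
    redundancy filtering, six relevance selectors (rank-sum p-value, LASSO,
    semi-supervised LASSO, PCA, semi-supervised PCA, sequential forward
    selection), per-class SMOTE augmentation, a leave-one-out evaluation grid
    over five classifiers, and Shapley-value explanation of the final model
    with principal-component class attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
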