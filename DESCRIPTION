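Package: rdmap
Title: Voxel-Wise Radiomics and Radiomic Decision Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise engineered radiomics for multimodal 3D oncology
    imaging. Computes 77 first-order and texture (GLCM, GLDM, GLRLM, NGTDM)
    feature maps per modality with a 3D sliding window, aggregates them into
    region-of-interest feature vectors together with 14 mask-derived shape
    features, reduces multicollinearity by iterative pairwise-Pearson and
    variance-inflation-factor pruning, fits L1-regularized logistic models
    selected by forward search under repeated stratified cross-validation
    with an average stratified Brier score, validates them by permutation
    testing and bootstrap aggregation with out-of-bag ROC AUC, and
    backprojects the fitted coefficients into per-patient Radiomic Decision
    Maps whose region mean exactly reproduces the model's probabilistic
    output. Includes a multimodal tumor phantom generator (necrotic core,
    metabolically active rim) so the full pipeline runs without any
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
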