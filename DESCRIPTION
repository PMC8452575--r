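Package: ichradiomics
Title: CT Radiomics Pipeline for Intracerebral Haemorrhage Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end quantitative CT-radiomics workflow for predicting
    haematoma expansion and poor functional outcome after spontaneous
    intracerebral haemorrhage. Provides NIfTI volume and mask handling with
    isotropic resampling, a 13-image filter bank (Laplacian-of-Gaussian
    scales and stationary wavelet subbands), a 754-entry radiomics feature
    catalogue (first-order, shape, GLCM, GLRLM, GLSZM and NGTDM families),
    empirical-Bayes location-scale batch harmonisation across slice-thickness
    batches with strict train-then-apply semantics, iterative
    correlation-based feature elimination, elastic-net penalised logistic
    regression with stratified cross-validated AUC grid search, and
    ROC/Youden threshold evaluation with confidence intervals. A synthetic
    CT phantom and cohort generator makes every stage testable without
    clinical trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    glmnet,
    jsonlite,
    yaml,
    cluster,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    sva,
    withr
Config/testthat/edition: 3
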