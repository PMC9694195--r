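Package: dynrad
Title: Dynamic Radiomics of 4D Perfusion MRI for Stroke Outcome Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating dynamic radiomics models of
    4D dynamic susceptibility contrast perfusion-weighted MRI (DSC-PWI).
    The package simulates bolus-passage cohorts with whole-brain and
    ischemic-lesion regions of interest, extracts time-resolved radiomics
    features (first-order, GLCM, GLRLM, GLSZM, NGTDM and GLDM families over
    an 18-member derived-image bank), screens features with a Levene-gated
    two-sample t-test, selects outstanding features with a cross-validated
    Lasso cascade over whole-brain, lesion and combined feature sets, and
    compares the resulting feature groups across ten classifiers under
    stratified k-fold cross-validated AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    glmnet,
    data.table,
    jsonlite,
    yaml,
    RNifti,
    MASS,
    e1071,
    rpart,
    randomForest,
    xgboost,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
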