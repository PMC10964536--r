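Package: habitatRFA
Title: Habitat-Based Radiomics for Ablation Response in Lung Metastases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for habitat-based radiomics analysis of
    paired pre- and post-ablation CT volumes of lung metastases.
    Provides a seeded synthetic-cohort generator emulating radiofrequency
    ablation of colorectal-cancer lung metastases, isotropic resampling
    and intensity windowing, physical-unit peritumoral ring construction,
    K-means habitat mapping with Calinski-Harabasz cluster-number
    selection, IBSI-style geometry/intensity/texture feature extraction,
    a feature-selection cascade (ICC, Welch t-test, correlation pruning,
    mRMR, LASSO), cross-validated signature models, and evaluation
    statistics (DeLong AUC inference, Youden cutoffs, Hosmer-Lemeshow
    calibration, decision-curve analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    glmnet,
    RNifti,
    jsonlite,
    yaml,
    randomForest,
    ranger,
    xgboost,
    e1071,
    nnet,
    class,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
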