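Package: vascmap
Title: Cerebrovascular Morphology Phantoms and Blood-Pressure-Based
    Hypertension Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how cerebrovascular morphology relates to
    hypertension status. Generates synthetic angiographic phantoms with
    ground-truth vessel trees and class-conditional blood-pressure cohorts;
    preprocesses and segments bright-vessel volumes with adaptive local
    thresholding and 3-D region growing; extracts a 17-value vascular
    descriptor (radius-distribution bins plus surface-curvature statistics);
    labels subjects by systolic, diastolic and mean-arterial-pressure rules;
    balances classes with SMOTE; and benchmarks classifier/validation grids,
    reporting tidy results tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    MASS,
    e1071,
    rpart,
    randomForest,
    RNifti
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
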