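Package: tractclass
Title: Along-Tract Diffusion Profile Classification of MCI Conversion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Along-tract ("tractometry") classification of diffusion MRI
    tract profiles for predicting conversion from mild cognitive impairment
    to Alzheimer's disease. Provides AFQ-style streamline-bundle cleaning
    and 100-node tract-profile quantification, a nested leave-one-out
    cross-validated RBF-SVM classifier with recursive feature elimination
    and correlation-bias reduction, exact binomial chance-level and
    permutation-based screening of classifier accuracy, node-selection
    stability analysis with FDR-corrected node-wise group tests, definition
    of predictive tract regions, and a final region-restricted classifier.
    A synthetic-cohort generator with configurable localized group effects
    supplies ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    dplyr,
    jsonlite,
    readr,
    tibble,
    tidyr,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    pROC
Config/testthat/edition: 3
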