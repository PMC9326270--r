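Package: destchoice
Title: Destination-Choice Modelling for Virtual Pedestrian Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing stated destination choices from virtual
    pedestrian experiments in which participants visit up to five of six
    destinations under a hypothetical time budget. Implements a multinomial
    logit destination-choice model with per-decision normalised occupancy,
    distance and schedule-desirability predictors; maximum-likelihood
    calibration with AIC reporting; bootstrap confidence intervals,
    permutation tests on parameter differences and likelihood-ratio tests;
    two participant-clustering procedures (threshold clustering on
    normalised cumulative quantities and hierarchical clustering of
    per-individual parameter estimates); Levenshtein-distance scoring of
    schedule adherence; and a sequential-choice simulator that generates
    synthetic cohorts with known ground truth for method validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr,
    jsonlite
Config/testthat/edition: 3
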