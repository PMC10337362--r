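Package: tmtrace
Title: Digitized Trail Making Test Trajectory Analysis and Cognitive Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing pen trajectories recorded while subjects
    perform the Shape Trail Test (a Trail Making Test variant) on a
    digitizing tablet. Reads and validates raw sample streams (x, y,
    pressure, timestamp), segments pen-down strokes, and computes
    time-, pressure- and jerk-based kinematic features together with
    template-based features built from dynamic time warping and
    vector-quantized key points. Includes a cross-validated pairwise
    classification workflow for screening cognitive impairment
    (healthy control, mild cognitive impairment, Alzheimer disease),
    grouped permutation feature importance, and a synthetic cohort
    simulator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp,
    randomForest,
    e1071,
    xgboost,
    pROC
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
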