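Package: fluencynet
Title: Verbal Fluency Scoring and Semantic Network Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analyzing verbal fluency data: standardized scoring of
    fluency lists (cluster switches and sizes under fluid or static rules,
    perseverations, intrusions, word-level norms such as frequency and age of
    acquisition) and estimation of semantic networks from fluency lists by
    several methods (first-edge, naive random walk, pathfinder union of
    minimum spanning trees, correlation-based thresholding, windowed
    co-occurrence significance, and maximum-likelihood estimation under a
    censored random walk). Includes an exact first-passage likelihood for the
    censored-random-walk model, a seeded simulator that doubles as a
    synthetic-data generator with a planted ground-truth ledger, descriptive
    network statistics, canonical edge-list import/export, and reproducible
    batch reporting to CSV and JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
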