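Package: sleepscape
Title: Sleep Phenotype Landscapes from Wrist Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for digital sleep phenotyping from wrist
    acceleration: epoch-level sleep/wake classification from jerk
    power-spectrum features, nonwear detection, sleep-window construction,
    extraction of 21 per-subject sleep indexes (including chi-square
    periodogram period, coefficient-of-variation amplitude, and van der Pol
    limit-cycle phase), and divisive unsupervised clustering of sleep
    phenotypes (UMAP embedding, DBSCAN, Ward regrouping, and a percentile
    outlier branch). Ships a synthetic-cohort simulator with full ground
    truth so every stage is testable without device data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    jsonlite,
    yaml,
    deSolve,
    xgboost,
    mclust,
    uwot,
    Rtsne
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
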