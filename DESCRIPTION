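Package: pugenerank
Title: Stochastic Positive-Unlabeled Learning for Genome-Wide Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ranks every gene in a closed gene universe by its likelihood of
    association with a disease, starting from a gene-by-feature annotation
    table and a small set of positively labeled (seed) genes.  Implements a
    stochastic semi-supervised positive-unlabeled scheme: at each iteration
    the unlabeled gene space is partitioned into balanced datasets (seed
    sample to unlabeled ratio 1:1.5), each balanced set is scored by
    stratified k-fold cross-validation with one of seven classifier families,
    and out-of-bag prediction probabilities are aggregated into a
    genome-wide ranking.  Includes shadow-feature (Boruta-style) consensus
    feature importance, stepwise hypergeometric enrichment of top predictions
    against external ranked gene lists, seed-masking validation, and a
    synthetic-data generator with planted ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    yaml,
    stats,
    utils,
    ranger,
    xgboost,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
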