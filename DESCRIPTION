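Package: cardioselect
Title: Wrapper and Filter Feature Selection for Clinical Risk Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature selection toolkit for binary clinical classification
    tables in the UCI processed-Cleveland dialect. Implements a univariate
    filter stage (chi-square, mutual information, ANOVA F) with rank
    aggregation, three metaheuristic wrapper searches over feature subsets
    (genetic algorithm, binary particle swarm, ant colony optimization) driven
    by a random-forest wrapper fitness, and an evaluation harness with
    confusion-matrix metrics, rank-based AUC, stratified cross-validation and
    a pluggable classifier registry. Includes a synthetic cohort generator
    with known informative features for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    ranger,
    randomForest,
    e1071,
    rpart,
    nnet,
    class,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
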