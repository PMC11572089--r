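Package: nullnet
Title: Decision-Error Monte Carlo Simulation for Neural Networks on Null Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates the probability that a feed-forward neural network
    trained on data with no population-level association between ordinal
    independent variables and a continuous or binary dependent variable
    nevertheless reaches a nominally acceptable level of predictive
    performance (test-set R-squared, AUC, or balanced accuracy) on an
    independent test split. Provides a seeded generator for null and
    signal-injected Likert-style datasets, a minimal fully connected
    network engine (SELU activations, Adam optimiser, validation-based
    early stopping with best-weight restoration), test-set metrics with
    degenerate-run exclusion rules, and a condition-grid Monte Carlo
    driver with reference tables for sample-size planning.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    parallel,
    stats,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
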