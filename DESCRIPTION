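Package: brlearn
Title: Bayesian Rule Learning with Global and Local Structure Search
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Learns parsimonious probabilistic IF-THEN classification rules
    from continuous, high-dimensional data such as gene-expression matrices.
    Continuous features are discretized with a supervised Bayesian method
    (EBD), a target-centric Bayesian network is learned by beam search under
    the K2 score with either a fully expanded conditional probability table
    (global structure search) or a decision-tree parameterization that merges
    contexts with identical class distributions (local structure search), and
    the learned table is read out as a mutually exclusive and exhaustive rule
    base with smoothed posterior probabilities and odds. Includes a stratified
    cross-validation harness reporting AUC, accuracy, and parsimony metrics,
    a synthetic-data generator with planted rule structure, and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
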