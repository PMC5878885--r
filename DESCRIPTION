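Package: evospec
Title: Evolutionary Specification of Multilevel Categorical Predictors for
    Clinical Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for learning the level of specificity at which multilevel
    categorical predictors (such as emergency-department chief complaints
    nested within complaint categories) should enter a binary-outcome risk
    model. A genetic algorithm searches over binary masks that select specific
    complaints, scoring each candidate by the 5-fold cross-validated AUC of a
    logistic regression under either a flattened (mutually exclusive) or a
    hierarchical encoding of the two-level predictor. Includes DeLong tests
    for correlated AUC estimates, bullseye subgroup evaluation, predicted
    probability shift summaries, mask agreement and selection-stability
    analyses, and a synthetic emergency-department cohort generator with known
    ground truth for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
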