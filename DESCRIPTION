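Package: lprm
Title: LASSO-Based Item-Trait Pattern Recognition for Multidimensional
    Adaptive Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for detecting the item-trait
    patterns of replenished (pretest) items in multidimensional
    computerized adaptive testing (MCAT). Implements the compensatory
    multidimensional two-parameter logistic model, adaptive item selection
    by D-optimality and Bayesian A-optimality with MAP trait scoring,
    fixed-length and standard-error-based variable-length stopping rules,
    an L1-penalized logistic coordinate-descent solver with BIC pattern
    selection along a regularization path, relaxed refitting of item
    parameters under detected patterns, and the full set of recovery and
    exposure indices needed for Monte Carlo study of the method.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    glmnet,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
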