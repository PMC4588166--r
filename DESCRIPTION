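Package: twostepr
Title: Simulation and Hierarchical Modelling of the Two-Step Decision Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the two-step sequential decision task: a task and
    cohort simulator with drifting reward probabilities, hybrid
    model-free/model-based Q-learning likelihoods with softmax-plus-lapse
    action selection, hierarchical empirical-Bayes fitting by
    expectation-maximization with Laplace approximation, integrated-BIC
    model comparison, and the standard behavioural analyses (exclusion
    filters, lagged logistic regressions of choice, switch-stay tables,
    concurrent-task accuracy summaries).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
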