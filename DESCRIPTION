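Package: basketopt
Title: Utility-Based Optimization of Basket Trial Designs with Information Borrowing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tuning Bayesian basket trial designs that borrow
    information between strata through similarity weights on beta-binomial
    posteriors. Implements the borrowing design (Jensen-Shannon or Hellinger
    similarity, weighted posterior, posterior-probability test decision),
    exact enumeration and Monte Carlo computation of frequentist operating
    characteristics (per-stratum rejection rates, experiment-wise power,
    family-wise error rate, expected number of correct decisions), a family
    of twelve utility functions combining power and type-I error across
    outcome scenarios, and a suite of derivative-free optimizers (simulated
    annealing, differential evolution, grey wolf, COBYLA, grid search) with
    evaluation-budget accounting, plus runners for a pre-specified
    algorithm/utility comparison study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    nloptr,
    purrr,
    rlang,
    stats,
    tibble
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
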