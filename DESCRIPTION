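Package: pfbt
Title: Simulation and Computational Modelling of the Probabilistic False-Belief Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for simulating and modelling the probabilistic false-belief
    task (p-FBT), in which a participant tracks a drifting Bernoulli outcome
    probability while also predicting another agent's belief about it. The
    package generates task sequences (bounded random walks, three sampling-trial
    types, interleaved probe trials), implements a dual-agent reinforcement
    learning model in which prediction errors can "leak" between Self and Other
    belief representations, fits the model by maximum a posteriori estimation
    with a Beta response likelihood and Laplace-approximated model evidence,
    performs fixed- and random-effects Bayesian model comparison (protected
    exceedance probabilities), computes model-free outcome-belief correlation
    metrics with simulation-based null distributions, and orchestrates
    parameter- and model-recovery experiments over simulated cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
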