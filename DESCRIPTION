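Package: restlessbandit
Title: Explore/Exploit Modelling for Restless Four-Armed Bandit Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and hierarchical Bayesian analysis of behaviour in
    restless four-armed bandit tasks with decaying Gaussian random-walk
    payoffs. Implements Kalman-filter and Delta-rule learning models combined
    with four softmax choice rules (random exploration, uncertainty-bonus
    directed exploration, perseveration, and total-uncertainty random
    exploration), a synthetic-cohort generator with known ground truth,
    per-condition hierarchical Bayesian parameter estimation with
    Metropolis-within-Gibbs sampling, PSIS-LOO model comparison, model-based
    explore/exploit trial classification, model-free behavioural metrics, and
    trial-wise regressor export.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stats,
    utils,
    generics,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
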