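Package: bayescompare
Title: Bayesian and Frequentist Indices of Effect Existence and Significance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes seven indices used to describe the existence and
    significance of regression effects from posterior draws: the frequentist
    p-value, the probability of direction (pd), the MAP-based p-value, the
    percentage of the posterior (full or of its 95% highest density interval)
    inside a region of practical equivalence (ROPE), and two Bayes factors
    (Savage-Dickey density ratio against a point null, and against the ROPE).
    Ships a simulation engine for single-predictor linear and logistic
    datasets with controlled sample size, noise and true-effect presence, a
    self-contained adaptive MCMC sampler for the Bayesian fits, and
    meta-analysis tools that quantify each index's sensitivity to sample size
    and noise, so that the behaviour of the indices can be compared at desk
    scale.
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
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
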