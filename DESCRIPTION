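Package: popcircuit
Title: Multidimensional Models of Cortical Circuit Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for relating low-level neural circuit components to
    population activity statistics in layer 2/3 sensory cortex. Provides a
    conductance-based leaky integrate-and-fire network model of the barrel
    cortex microcircuit with a single-parameter perturbation sweep; a
    two-parameter logistic input-output model with analytic firing-rate and
    pairwise-correlation maps over a standard-normal input drive; a
    five-parameter population extension (2D Gaussian over slope and
    threshold) fitted to activity statistics by accept/reject stochastic
    descent; Poisson binarization of calcium-derived firing rates; entropy
    estimation for large populations via the population tracking model with
    double-exponential extrapolation; bootstrap group tests and chi-squared
    confidence ellipses; and a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    pracma,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
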