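Package: rrddm
Title: Reward-Rate Optimality Analysis with the Drift-Diffusion Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether decision-makers set reward-rate-optimal
    decision thresholds in two-alternative forced-choice tasks. Implements the
    full drift-diffusion model (between-trial variability in drift rate,
    starting point and non-decision time) with a fast first-passage-time
    density and an Euler simulator; simulation-based and closed-form
    computation of the reward-rate-maximising threshold; hierarchical Bayesian
    estimation of block-varying-threshold and distance-from-optimality models
    via differential-evolution MCMC; Savage-Dickey density-ratio Bayes factors
    with directional (truncated-prior) variants; and a synthetic-experiment
    generator for fixed-time and fixed-trial block designs with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
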