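Package: nof1sim
Title: Simulation-Based Operating Characteristics of Aggregated N-of-1,
    Crossover and Parallel Trial Designs
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates aggregated N-of-1 trials, two-period crossover
    trials and parallel randomized controlled trials from a common
    random-intercept linear mixed model, and estimates their operating
    characteristics (empirical power, type-I error, carryover-effect
    inflation, selection-bias inflation, and random-effect-based
    subgroup separation) by Monte Carlo. Inference for the repeated
    measures designs uses a maximum-likelihood random-intercept fit
    with the variance ratio profiled out, a deviance-based
    likelihood-ratio chi-squared test for the treatment effect, and
    empirical-Bayes (BLUP) random-effect predictions; the parallel
    design is analyzed by ordinary least squares. Includes experiment
    drivers for power-versus-sample-size and power-versus-effect-size
    grids, carryover and non-representative-sampling experiments, and
    a YAML-configurable command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
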