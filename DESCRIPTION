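Package: fairddm
Title: Drift-Diffusion and Mixed-Model Analysis of Incentivised Fairness
    Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates and analyses third-party punishment and compensation
    decisions in a two-alternative dictator game with trial-wise monetary
    incentives. Provides a generator for the full experimental design
    (allocation options, incentive levels, observation phase, control trials,
    payouts) and for synthetic participants under either a Wiener diffusion
    or a logistic generative model; a Wiener first-passage-time likelihood
    kernel; hierarchical Bayesian drift-diffusion model estimation by MCMC
    with Gelman-Rubin diagnostics; DIC-based model selection with model
    averaging and posterior exceedance tests; confirmatory logistic mixed
    models; and a simulation-based power analysis for the confirmatory
    design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    lme4,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
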