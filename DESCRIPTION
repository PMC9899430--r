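Package: ddvar
Title: Variance Decomposition for Density-Regulated Stochastic Population Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and Bayesian inference tools for studying how density
    regulation interacts with environmental stochasticity in discrete-time
    population dynamics. Simulates stochastic Gompertz (AR(1) on the log
    scale) and Ricker trajectories, provides the closed-form stationary
    moments of the Gompertz model and the decomposition of its stationary
    variance into environmental and density-dependent components, fits both
    models by Markov chain Monte Carlo with Gelman-Rubin convergence
    diagnostics, and orchestrates replicated simulation experiments that
    quantify the share of population variability attributable to density
    feedback.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
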