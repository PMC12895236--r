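Package: fluctcomm
Title: Stochastic Lotka-Volterra Communities with Fluctuating Growth Rates
Version: 0.1.0
Authors@R:
    person("Robin", "Seaton", email = "robin.seaton@posteo.net",
           role = c("aut", "cre"))
Description: Simulation and statistics for species-rich communities whose
    per-capita growth rates fluctuate as Ornstein-Uhlenbeck (coloured) noise
    within a Lotka-Volterra competition framework, with excess
    self-regulation, immigration, an extinction cutoff, and dispersal among
    metacommunity patches. Includes the exact replicator-equation solution as
    an internal oracle, a focal-species effective model whose fast-environment
    stationary abundance distribution is a generalised inverse Gaussian
    (power law with upper and lower bends), tools to estimate effective noise
    statistics from trajectories and fit abundance distributions, and
    community summaries: Simpson effective richness, dominance time,
    species- and frequency-abundance histograms, shape indices, Bray-Curtis
    turnover decay, and Buffering-Stabilisation coordinates. A config-driven
    command-line interface reproduces the model's reference experiments.
License: GPL-3
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
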