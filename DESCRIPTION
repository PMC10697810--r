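Package: bottleneckR
Title: Optimal Bottleneck Regimes for Adaptation in Serially Passaged
    Microbial Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Theory and stochastic simulation of how the severity (D) and
    frequency (growth period tau) of population bottlenecks determine the
    rate at which beneficial mutations fix in serially passaged microbial
    populations. Provides closed-form and numerically evaluated adaptation
    rates for exponential and Monod resource-limited growth, branching
    process survival probabilities, the eight classical model variants
    (per-time vs per-transfer optimization, stochastic vs deterministic
    growth, binomial vs Poisson bottleneck sampling), exact stochastic
    simulators of serial passage, chemostat and multi-locus (clonal
    interference) regimes, and sweep/optimization utilities for choosing
    dilution regimes in experimental evolution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
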