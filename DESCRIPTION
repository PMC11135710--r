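Package: diauxie
Title: Serial-Dilution Simulation of Diauxic Resource Competition and
    Temporal Niches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Exact event-driven simulation of microbial communities that
    consume resources sequentially (diauxie) under periodic boom-and-bust
    growth cycles with mortality and resource resupply.  Provides samplers
    for random species pools under an L2 metabolic constraint, stochastic
    and seasonal resource-supply schedules parameterised by a fluctuation
    magnitude, temporal-niche extraction and tallying, the combinatorial
    bound on coexisting species, constrained-optimal growth strategies,
    and experiment drivers for competitive-exclusion-violation sweeps,
    diversity-versus-resources scaling with model fitting, and dynamics
    classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    yaml,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
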