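Package: trailnet
Title: Trail-Laying Robot Swarms in Corridor Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of collective path selection by groups of
    trail-laying, trail-following agents (ant-like robots) in diamond-loop
    corridor networks. Provides the three-loop maze geometry in symmetrical and
    asymmetrical configurations, a continuous-space behavioural simulator with a
    virtual pheromone raster (disc deposition, capped accumulation, exponential
    evaporation), a discrete stochastic network-choice model separating
    pheromone and geometry effects, and the analysis pipeline that classifies
    which path a swarm has collectively selected over time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
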