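Package: paradigmflow
Title: Multi-Agent Simulation of Paradigm Shifts on a Quartic
    Physical-Technological Landscape
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a homogeneous community of knowledge agents
    exploring a one-dimensional quartic "physical-technological"
    landscape with two hills: a local optimum (the current paradigm)
    and a higher global optimum (the new paradigm). Each agent combines
    individual gradient ascent, peer-sampled social influence and
    Gaussian experimentation noise in a Langevin-type evolution
    equation integrated by Euler-Maruyama. The package measures the
    community first-passage ("paradigm shift") time from the old to the
    new optimum, sweeps the social-influence weight alpha and the
    population size, detects the characteristic three-regime shape of
    the mean shift-time curve, and provides a single-agent
    first-passage oracle, reproducible seeded replicate batches,
    JSON-configured runs with manifests, figures, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    ggplot2,
    rlang,
    survival,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
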