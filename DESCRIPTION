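Package: dgnet
Title: Dentate Gyrus Microcircuit Simulation and Small-World Network Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generates topographic connectivity for a reduced dentate gyrus
    microcircuit (granule, mossy, basket and HIPP cells) in a healthy or a
    pathological (mossy-fiber-sprouting / mossy-cell-loss) configuration,
    simulates the network with multicompartment conductance-based neuron
    models under a perforant-path stimulation protocol, and quantifies the
    small-world character of the resulting connectivity (clustering
    coefficient, characteristic path length, equivalent-random-graph
    reference and small-world quotient).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    deSolve,
    withr,
    optparse
Config/testthat/edition: 3
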