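Package: aquarisk
Title: Landscape-Scale Aquatic Pesticide Exposure and Effect Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pesticide risk to aquatic invertebrates across a river
    catchment: stochastic spray-drift deposition from orchards onto a reach
    network, hourly water-sediment fate with advective routing through the
    network, reduced GUTS (General Unified Threshold model of Survival)
    toxicokinetic/toxicodynamic survival modelling, and LP50
    margin-of-safety end points. Includes a synthetic dendritic catchment
    generator so the full chain runs without external geodata, plus
    landscape-scale risk characterisation: annual peak concentration
    tables, pooled percentiles, spatiotemporal rank matrices, and
    worst-year LP50 category maps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
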