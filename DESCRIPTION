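Package: aquaflux
Title: Oocyte Swelling, Relative Expression, and Excretion Analysis for
    Aquaporin Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis chain for functional characterization of aquaporin
    water and solute channels. Provides a forward model of Xenopus oocyte
    swelling under osmotic and solute gradients, estimation of the osmotic
    water permeability coefficient (Pf) and solute permeability coefficient
    (Ps) from cross-sectional area time courses via initial-slope fits,
    relative gene expression by the 2^(-ddCt) method with an amplification
    efficiency gate, blood-meal excretion, urea and fecundity phenotype
    endpoints with the matching group statistics, and seeded synthetic-data
    generators that emulate each assay for testing and power analysis.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
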