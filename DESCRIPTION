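Package: vinehydro
Title: Xylem Vulnerability, Pressure-Volume and Hydraulic Conductance
    Analysis for Drought-Acclimated Grapevines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of plant hydraulic acclimation to water deficit:
    sigmoidal xylem vulnerability curves (PLC50, Psi12/Psi88, midpoint
    slope, bootstrap confidence intervals, linearized treatment
    comparison), Turner-style pressure-volume curve parameter extraction
    (osmotic potential at full turgor, bulk modulus of elasticity, turgor
    loss point, apoplastic fraction), Hagen-Poiseuille theoretical
    conductivity from vessel anatomy with leaf-area normalization and
    vessel size-class distributions, Ohm's-law leaf and whole-plant
    hydraulic conductances with water-potential-class binning, and
    seeded synthetic-data generators so every stage is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
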