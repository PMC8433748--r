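Package: cmcfit
Title: Critical Micelle Concentration Determination with a Surfactant
    Concentration Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines the critical micelle concentration (cmc) and the width
    of the micellization transition from titration data of any solution
    property. A closed-form concentration model gives monomer and micellized
    surfactant concentrations as functions of total concentration with two
    parameters, the cmc and the relative transition width; forward models for
    conductivity, surface tension, NMR chemical shift, dye fluorescence,
    pyrene band ratio, UV-Vis absorbance, tracer diffusion and peptide
    aggregation are built on it and fitted to data by damped nonlinear least
    squares, individually or globally with shared parameters. Classical
    graphical and derivative estimators and the Boltzmann-sigmoid conductivity
    model are included for comparison, together with a seeded synthetic-data
    generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
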