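Package: rhizosim
Title: Single-Root Exudation Gradients in Depth-Dependent Peat Soil
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the radial accumulation gradient of root exudates
    around a single cylindrical root segment in saturated peat.
    Concentration-dependent efflux and influx at the rhizoplane (passive
    permeation, Michaelis-Menten uptake, and a Goldman-type flux for
    charged solutes) are coupled to Fickian diffusion through concentric
    soil annuli, Langmuir sorption to the solid phase, and first-order
    microbial mineralization. Soil properties (bulk density, porosity,
    Archie tortuosity, temperature, microbial biomass) follow
    depth-dependent profiles parameterised for an ombrotrophic bog, so
    equilibrium net exudation, rhizoplane concentration, and rhizosphere
    extent can be compared across soil depths. Includes Sobol-sequence
    global sensitivity sampling and partial rank correlation coefficient
    (PRCC) analysis of the model outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
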