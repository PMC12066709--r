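Package: grainDBL
Title: Anoxic Microenvironments and Denitrification on Single Sand Grains
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies how patchy microbial oxygen consumption and
    production on the surface of single sand grains creates anoxic
    microenvironments inside the diffusive boundary layer, and how much
    denitrification those microenvironments contribute to nitrogen loss
    from permeable shelf sediments.  Provides ratiometric optode image
    calibration and volumetric oxygen rate mapping, grain-size and
    surface-roughness statistics, a two-dimensional single-grain flow and
    reactive-transport model with Michaelis-Menten oxygen kinetics and an
    oxygen-inhibited denitrification source, a Damkoehler-type
    boundary-layer scaling (the Sand_DBL number) with a fitted
    anoxic-fraction power law, and an areal upscaling of denitrification
    fluxes from site parameter tables.  Seeded synthetic-data generators
    emulate every input so the full pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
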