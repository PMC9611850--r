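Package: vinefuse
Title: Multi-Resolution NDVI Fusion and Field Advice for Row Crops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Raster-analysis toolkit for precision viticulture. Decomposes
    decametric satellite NDVI into whole-cell, canopy and inter-row components
    by matching centimetric UAV pixel centres to satellite pixel footprints,
    segments vine canopy from inter-row soil, fuses covariate-derived soil
    moisture by ordinary kriging calibrated against in-situ point sensors, and
    turns the fused layers into irrigation/fertilisation attention points with
    a genetic-algorithm route planner. Ships a synthetic vineyard-scene
    simulator so every stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    EBImage,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
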