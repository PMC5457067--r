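Package: strandwidth
Title: Line-Width Prediction for Pneumatic Extrusion Bioprinting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models the resolution of pneumatic extrusion bioprinting as
    capillary flow of a power-law (Ostwald-de Waele) fluid. Fits the
    power-law viscosity model to rheometer flow curves, predicts the
    printed strand width from nozzle geometry, gauge pressure and stage
    speed via the Rabinowitsch-corrected capillary-flow chain, inverts the
    prediction for process design (required pressure or speed for a target
    width), and compares predictions against measured print-run tables.
    Ships published pluronic F127 ink constants and line-width
    measurements as plain-text fixtures, plus a seeded synthetic-data
    generator for flow curves and print runs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
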