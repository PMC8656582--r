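Package: fluorowell
Title: Single-Cell Microwell Fluorospot Simulation and Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward simulation and end-to-end image analysis for single-cell
    secretion assays on self-seeding microwell arrays with serial antibody
    capture membranes. Generates ground-truth experiments (cell occupancy,
    lognormal secretion rates, drug-response phenotypes, viability, rendered
    fluorescence mosaics and calibration standards), and recovers them with a
    per-well cell detector, rigid membrane-to-chip registration, saturating
    calibration-curve inversion to absolute secreted mass, per-cell secretion
    rates, time-series response classification, and the assay's paired
    nonparametric statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
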