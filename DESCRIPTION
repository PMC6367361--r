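Package: mechanocyte
Title: Cell Biomechanics and Quantitative Microscopy Assay Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of single-cell biomechanics and motility experiments on
    adherent cells. Fits the Hertz-Sneddon contact model to atomic force
    microscopy (AFM) force-distance curves to estimate per-cell Young's
    moduli, assembles per-pixel stiffness and setpoint-height maps from force
    maps and segments them into cells, converts quantitative phase images to
    dry-mass maps, extracts cell morphometrics (circularity, feret diameter,
    roundness, aspect ratio) and stress-fibre orientation statistics,
    quantifies colony-forming, impedance-based (cell index) and migration
    assays, and dispatches the normality-gated statistical tests used in this
    field. Includes seeded synthetic-data generators with ground truth for
    every input modality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    jsonlite,
    tiff,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
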