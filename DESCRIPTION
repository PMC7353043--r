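Package: sparkdrop
Title: Single-Cell Quantification of Droplet-Forming PKA Biosensor Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantification pipeline for phase-separating
    protein kinase A (PKA) activity biosensors of the SPARK family, which
    report kinase activity as bright fluorescent droplets. Provides a
    synthetic-population and time-lapse image generator (heterogeneous
    biosensor expression, a cAMP-capable subpopulation, hormone-specific
    responder subsets with nested overlap, transient/sustained/dissolving
    droplet kinetics), rolling-ball background subtraction implemented as a
    grayscale morphological opening, cell segmentation with expression
    gating, droplet detection with three per-cell droplet statistics
    (droplet/cell intensity ratio, within-cell intensity SD, total droplet
    area), responder calling with population shares, sequential-stimulation
    overlap and clone-level summaries, and a zero-expression census of
    adenylyl cyclase genes on sparse single-cell count matrices.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    graphics,
    jsonlite,
    methods,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
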