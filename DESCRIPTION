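Package: cellforce
Title: Membrane Force Estimation from Cell Migration Time-Lapse Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-cell tracking and membrane force estimation for time-lapse
    microscopy of migrating cells. Fits a forced, volume-constrained Allen-Cahn
    (phase-field) model to segmented image sequences by PDE-constrained optimal
    control with an exact discrete adjoint, returning the spatio-temporal
    protrusion/retraction force on the cell membrane together with geometric
    summaries: membrane length, centroid, and a diffuse-interface Euler number
    that counts cells and detects division or fusion events. Includes a
    segmentation front end (Otsu thresholding combined with edge detection),
    synthetic movie generators for validation, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    EBImage,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
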