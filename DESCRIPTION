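Package: nucquant
Title: Quantification of Nuclear Staining in Brightfield and Fluorescence Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-cell quantification of nuclear antibody staining in
    haematoxylin/DAB brightfield images and two-channel fluorescence images.
    Nuclei are segmented by histogram auto-thresholding and size-gated
    connected-component analysis (or ingested as externally produced masks),
    antibody signal is thresholded independently, and each nucleus is called
    positive when the signal covers at least a configurable fraction of its
    area (default 80%). Field-level outputs include the percentage of positive
    nuclei, semiquantitative intensity classes with histoscore and an overall
    intensity category, and quantitative per-nucleus mean intensities.
    Includes H-DAB colour deconvolution, the ImageJ-style suite of 17
    automatic threshold selection algorithms, rater-agreement statistics
    (two-way absolute-agreement intraclass correlation), a coverage-threshold
    calibration sweep against rater consensus, a seeded synthetic-field
    generator with exact per-nucleus ground truth, and batch processing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    tiff,
    png,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
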