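Package: stretchCa
Title: Quantification of Stretch-Activated Calcium Signalling in Adherent Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A high-content analysis pipeline for fluorescence time-lapse
    recordings of calcium-indicator-loaded cells subjected to isotropic
    substrate stretch. Provides dark/flat-field correction, phase splitting,
    drift registration, watershed cell segmentation with cross-phase ROI
    mapping, relative-trace normalisation with peak-excluded baseline
    estimation, prominence-based peak detection, rule-based single-cell
    response classification (spontaneously active, stretch-activated, random
    peaks, silent), per-sample summaries and normality-gated group
    comparisons. Includes a synthetic scene and trace generator with full
    ground truth so that every stage is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    withr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBasedAssays, Software, Visualization
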