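Package: evmrm
Title: Targeted MRM Quantification and Validation of Extracellular Vesicle Marker Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for targeted liquid chromatography tandem mass spectrometry
    (LC-MS/MS) quantification of extracellular vesicle (EV) protein markers by
    multiple reaction monitoring (MRM). Implements a five-protein panel (CD9,
    CD81, TSG101 as positive EV markers; albumin and calnexin as contaminant
    markers), Gaussian chromatographic peak detection and integration with
    signal-to-noise estimation, stable-isotope-label (SIL) normalized
    quantification with single-point and external linear calibration, full
    bioanalytical validation (LOD/LLOQ from signal-to-noise, precision,
    repeatability, accuracy, carryover, short-term stability, matrix effects
    via absolute and relative SIL recovery, matrix-adjusted limits),
    hierarchical isolation/digest reproducibility statistics, and MISEV-style
    positive/negative marker reporting. A seeded simulator generates
    chromatograms and complete study designs with known ground truth for
    method verification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
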