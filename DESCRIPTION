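Package: adhesiondyn
Title: Quantification of Cell-Substrate Adhesion Dynamics from
    Fluorescence Timelapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and tracks fluorescent cell-substrate adhesion
    punctae in timelapse microscopy, fits assembly (logistic) and
    disassembly (exponential decay) kinetics to per-punctae intensity
    traces to estimate adhesion duration, lifetime and turnover rates,
    analyses fluorescence recovery after photobleaching (FRAP) curves
    for recovery half-times and immobile fractions with robust outlier
    removal (ROUT), and provides replicate-aware nonparametric group
    statistics with SuperPlot-style aggregation.  A seeded synthetic
    microscopy simulator with ground-truth tables supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    nortest,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
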