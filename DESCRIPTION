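Package: calquant
Title: Automated Single-Cell Quantification of Global Calcium Responses
    from Time-Lapse Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated, simultaneous single-cell and
    population-level quantification of global intracellular calcium
    responses recorded as single-channel time-lapse fluorescence movies
    of non-excitable cells (e.g. Fluo-4-loaded lymphocytes) landing on a
    stimulating surface. The pipeline segments and tracks individual
    cells with feature detection and distance-regularized level-set
    evolution, detects landing by cessation of movement, extracts
    per-cell intensity traces, smooths them with Savitzky-Golay
    filtering, normalizes to R(t) = I(t)/Imax, locates landing and
    triggering events as peaks in dR/dt, classifies responders by
    fold-increase over baseline, and aggregates responder fractions,
    mean response curves and triggering-interval distributions. A
    ground-truth synthetic movie generator makes every stage testable by
    parameter recovery without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    signal,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
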