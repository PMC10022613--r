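Package: cavistress
Title: Runaway Cavitation, Optical Embolism Detection and Dehydration
    Thresholds in Leaves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking xylem cavitation to lethal leaf dehydration:
    a sigmoidal leaf vulnerability curve with a closed-form runaway-cavitation
    point and a matching numerical supply-demand oracle, a capacitance-based
    drydown simulator, optical-vulnerability-style event detection and
    vein-order quantification in time-lapse leaf image stacks, two-segment
    (breakpoint) regression for fluorescence and leaf-width time series,
    rehydration-kinetics and pressure-volume curve estimators, and a seeded
    synthetic-data generator that emulates whole-plant drydown experiments so
    the full pipeline can be exercised end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
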