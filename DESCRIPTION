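Package: dragkinetics
Title: Drag-and-Drop Touch Kinetics as Digital Biomarkers for Developmental Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for drag-and-drop touchscreen gesture logs used as
    digital biomarkers of child development. Generates two-cohort synthetic
    touch-event sessions, extracts per-axis velocity/acceleration series and
    sign-change volatility features, runs a normality-routed two-group
    comparison protocol with common language effect sizes, trains and
    cross-validates a joint-fusion 1D convolutional classifier implemented in
    native R, and produces Grad-CAM attributions mapped back onto touch
    coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
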