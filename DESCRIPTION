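Package: stagecal
Title: Positioning-Error Calibration and Compensation for Motorized Microscope Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Models and compensates the systematic positioning errors of a
    camera-on-microscope motorized X-Y stage: second-order radial lens
    distortion calibrated by a plumb-line (line-straightness)
    Levenberg-Marquardt fit on grid images, camera mounting deflection
    estimated by stitching overlapping frames taken across stage steps,
    and signed per-axis mechanical displacement errors estimated from
    stepped image series.  The calibrated coefficients are assembled into
    a compensation model that converts desired physical displacements into
    corrected stage commands.  A synthetic grid-image simulator provides
    ground truth for every estimator, enabling closed-loop single-shot and
    cumulative-error evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    png,
    tiff,
    stats,
    graphics,
    grDevices,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
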