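Package: pedotherm
Title: Plantar Foot Temperature Dynamics During Walking
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for plantar skin temperature during a
    timed walk. Extracts per-region mean temperatures and areas from
    thermal frames with label masks, forms the area-weighted whole-foot
    temperature series, fits and compares linear and six-parameter
    generalized logistic (Richards) temporal models via
    Levenberg-Marquardt least squares, and partitions the observed
    temperature rise into a mechanical contribution (net foot work per
    stride accumulated over the stride count) and a physiological
    residual, with bound envelopes and a first-degree-burn time
    extrapolation. Includes a seeded synthetic-data generator producing
    regional series and matching thermal frames so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    png,
    optparse
Config/testthat/edition: 3
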