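Package: cigrscreen
Title: Time-Resolved Analysis of Impedance-Based Cell Proliferation Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of real-time cell analysis (RTCA) impedance screens in
    96-well plates. Provides cell-index normalization, the cell-index growth
    rate (CIGR) first-derivative transform, time-dependent Z-factor assay
    quality curves, plate-wise and time-series z-score normalization,
    constant-modulator ranking and thresholded run-length ("flooding
    watershed") detection of transient proliferation modulators, together
    with a seeded generator of synthetic impedance screens for validation
    at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
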