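Package: dosesim
Title: Dose-Reduction Simulation for Digital Mammography via the
    Anscombe Transformation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates reduced-dose digital mammograms from raw
    ("for processing") standard-dose acquisitions by injecting
    signal-dependent quantum noise in a variance-stabilized domain.
    The image is linearized against the detector offset, scaled by the
    mAs ratio, and noise estimated locally from flat-field exposures at
    the standard and target doses is embedded through the Anscombe
    transformation, so that the inserted noise acquires the correct
    dependence on the local signal and on the position in the field.
    Includes flat-field offset/linearity calibration, local variance
    mapping, noise power spectrum (NPS/NNPS) estimation with
    band-restricted radial profiles, crossed-comparison validation
    statistics, and a synthetic a-Se detector and breast-texture
    phantom simulator for end-to-end testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tiff,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
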