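Package: gazeframe
Title: Reference-Frame Analysis of Saccade Direction Biases Under Head Tilt
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the reference frame of saccade direction
    biases in free-viewing eye-tracking experiments with head roll tilt.
    Detects saccades from raw gaze traces with a robust velocity-threshold
    algorithm, builds circular kernel density estimates of saccade
    directions, estimates the angular displacement between condition pairs
    by circular cross-correlation with bootstrap confidence intervals,
    and summarises reference-frame anchoring with a reference frame index,
    including a variant scaled by ocular counter-roll measured from the
    torsion channel. Ships a seeded synthetic gaze simulator emulating a
    head-tilt free-viewing design so the full pipeline is testable without
    recorded data, and a small command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
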