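Package: stridesense
Title: Stride Lengths from Foot-Mounted IMUs During Sprint Acceleration
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates stride lengths, durations and speeds during maximal
    linear sprint acceleration from foot-mounted inertial measurement units.
    Implements gradient-descent (Madgwick) quaternion orientation estimation,
    gait-event detection from the medial-lateral gyroscope axis, and a
    zero-velocity-update double-integration scheme that corrects the velocity
    offsets caused by touch-down impact artefacts. Includes a synthetic sprint
    simulator with known ground truth for validation, Bland-Altman agreement
    statistics accounting for repeated measures within participants, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    stats,
    utils,
    yaml,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
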