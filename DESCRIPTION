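Package: heelraiser
Title: Heel-Raise Exercise Monitoring from Smart-Insole Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for monitoring heel-raise rehabilitation exercise from
    low-cost smart-insole recordings (four force-sensing-resistor channels
    plus a 3-axis accelerometer at 30 Hz), optionally alongside reference
    foot-orientation, surface-EMG and grid-pressure streams. Detects heel
    raise repetitions by thresholding foot pitch and splits each into rise,
    hold and drop phases from the pitch gradient; computes medial partial
    pressure, medio-lateral centre of pressure and EMG waveform-length
    features; phase-percent time normalisation with across-event ensemble
    mean and standard deviation; and eversion/inversion posture
    classification with optional per-subject calibration. Includes a
    ground-truth-labelled synthetic multi-sensor session generator
    emulating the cued exercise protocol, so the full pipeline is testable
    without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
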