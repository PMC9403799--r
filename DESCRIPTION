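Package: wingbeatr
Title: Wingbeat Kinematics and Flight State from Body-Mounted Biologgers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates tri-axial accelerometer, magnetometer, position and
    barometric pressure streams from a parametric flapping-flight model, and
    recovers per-wingbeat frequency and heave amplitude with a peak-detection
    algorithm based on smoothed heave acceleration and its second difference.
    A wing-mounted magnet gives a magnetometer vector-sum proxy for wingbeat
    amplitude. Barometric altitude, climb rate and wind-triangle airspeed are
    derived on the same timeline, and the statistical layer fits
    amplitude-frequency regressions, linear mixed-effects models with
    continuous-time AR(1) errors, and species-level coefficient-of-variation
    versus morphology correlations, including a bundled seabird morphometrics
    table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    nlme,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
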