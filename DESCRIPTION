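Package: mobsense
Title: Vertical Kinematics and Device Agreement for Instrumented Mobility Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for instrumented sit-to-stand (STS) and
    timed-up-and-go (TUG) trials recorded with a head-worn position sensor
    (around 30 Hz, jittered clock) and body-worn inertial units (128 Hz,
    gravity-corrected acceleration). Provides resampling and zero-phase
    Butterworth filtering, double integration of vertical acceleration with
    drift correction by high-pass filtering and zero-displacement updates
    (ZDU) at chair contacts, cross-correlation time alignment, signal
    agreement statistics (normalized RMSE, zero-lag cross-correlation,
    Bland-Altman limits of agreement), clinical mobility features (task
    durations, phase times, peak velocity and acceleration), and a
    minimum-jerk motion simulator with configurable sensor noise and bias
    drift for validating every stage against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
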