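Package: fogdetect
Title: Real-Time Freezing-of-Gait Detection and Gait Metrics from Lower-Leg IMU Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of freezing of gait (FOG) in Parkinson's disease from
    lower-leg inertial measurement unit (IMU) recordings, designed around the
    constraints of an embedded closed-loop cueing device. Provides spectral
    window features (freeze index, band power, variance, L1/L2 norms, spectral
    entropy) computed either batch (FFT) or streaming via a sliding discrete
    Fourier transform; a cost-weighted random-forest FOG classifier with
    leave-one-subject-out evaluation and ROC analysis; gyroscope-based step
    detection; stride-length estimation by drift-corrected double integration
    with zero-velocity updates; gait metrics from video-annotation event logs
    (step frequency, symmetry index, freeze counts and durations, observer
    agreement); a simulated closed-loop responsive-cue controller; and a
    synthetic labeled IMU gait generator so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    rpart,
    signal,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
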