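Package: gyrospec
Title: Ultralight Airborne Imaging Spectroscopy Simulator for Invasive
    Plant Detection
Version: 0.1.0
Authors@R:
    person("Gyrospec", "Developers", email = "gyrospec@example.org",
           role = c("aut", "cre"))
Description: Desk-scale simulator and analysis pipeline for pushbroom
    hyperspectral imaging of invasive plant patches from an ultralight
    aircraft. Generates synthetic terrain, clonal patch maps and a
    200-band (380-1000 nm) spectral library with realistic within-class
    variability; simulates unstable flight trajectories with noisy
    GPS/IMU streams fused by a Kalman-filter attitude and heading
    reference system (AHRS); forward-models line-scan cube acquisition
    with sub-pixel spectral mixing; performs parametric geocorrection by
    ray-DTM intersection plus ground-control-point residual correction;
    classifies pixels with a full-band RBF support vector machine; and
    assesses detection accuracy with error matrices, user's/producer's/
    overall accuracy and Cohen's kappa at a sub-pixel coverage
    threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
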