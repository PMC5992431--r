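Package: mentalstate
Title: Personalized Physiological Biometrics for Mental Fatigue, Stress, and Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds personalized models of three mental-state biometrics
    (mental fatigue, stress, attention) from EEG and ECG recordings taken
    during simple calibration tasks (breath counting and N-back recall).
    Provides signal preprocessing (notch and high-pass filtering, outlier
    channel rejection, iterative independent-component artifact removal
    under a signal-quality index, spherical-spline interpolation,
    moving-average drift correction), windowed EEG band-power and
    heart-rate-variability spectral features, per-electrode binomial-logit
    committee classifiers, a three-level validation scheme (balanced k-fold
    cross-validation, leave-one-out bounds with an intermediate-task
    regression test, and a permutation test of biometric-performance
    correlations on a novel task), and a synthetic-data generator with
    ground-truth latent states for end-to-end testing and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
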