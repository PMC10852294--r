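Package: crisptex
Title: Instrumental Crispness Analysis and Sensory Prediction by Gaussian
    Process Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates instrumented two-compression chew recordings (force,
    probe vibration, air-conduction sound) and sensory-panel line-scale
    scores for crisp snack foods; extracts 66 texture features per trial
    (texture profile analysis from the force curve, noise-gated peak-train
    and octave-band statistics from the vibration channel, psychoacoustic
    and A-weighted one-third-octave features from the sound channel); masks
    features by sensory condition; and predicts panel-mean texture scores
    with a Gaussian process regression evaluated by leave-one-out
    cross-validation and mean absolute error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
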