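Package: landstab
Title: Landing Stabilisation and Muscle Activity Analysis from Wearable Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing gymnastics landings recorded with a lower-back
    inertial sensor and lower-limb surface electromyography. Detects foot-floor
    contact from the accelerometer flight/impact signature, computes dynamic
    stability indices (root-mean-square deviation from a terminal quiet-stance
    baseline) and time to stabilisation (sequential-average method) over 3-s and
    1-s post-contact windows, reduces EMG to 30-node integrated normalised
    activity patterns around contact, and compares outcomes across motor task
    and gaze direction with fully within-subject two-way ANOVA at the scalar
    level and permutation-based statistical parametric mapping at the waveform
    level. Includes a synthetic trial generator with known ground truth so the
    whole pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    graphics,
    jsonlite,
    signal,
    stats,
    tibble,
    utils
Suggests:
    nortest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
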