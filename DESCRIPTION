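Package: pitcherp
Title: ERP Correlates of Musical Pitch from Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for event-related potential
    (ERP) studies of musical pitch. Generates synthetic multichannel EEG
    experiments with a pitch-linear, hemispherically anti-symmetric evoked
    amplitude effect; preprocesses continuous recordings (notch and bandpass
    filtering, correlation-based bad-channel detection, spherical-spline
    interpolation, surface-Laplacian re-referencing, artifact subspace
    reconstruction); selects a discriminative analysis window by a
    Davies-Bouldin-style separability index over sliding windows; and runs
    the inferential battery (ANOVA channel selection with bilateral
    completion, paired hemispheric tests, amplitude-vs-pitch slope fits,
    frontal-parietal asymmetry contrasts, group and behavior statistics)
    with false-discovery-rate control.
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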