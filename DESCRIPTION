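Package: headrec
Title: Detection of Soccer Headers from Wearable Head-Impact Sensor Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying triggered head-impact sensor events from
    soccer matches into true headers and spurious recordings. Provides a
    simulator for triggered 3-axis linear-acceleration events with xPatch-style
    trigger semantics (8 g resultant threshold, 10 ms pre-trigger / 90 ms
    post-trigger at 1000 Hz), video-verified ground-truth labelling by
    time-window matching, pink-noise class balancing, a bidirectional LSTM
    sequence classifier trained with moving-average adaptive moment updates,
    Gaussian-process Bayesian hyperparameter tuning with expected improvement,
    acceleration-threshold baselines, and a balanced/unbalanced evaluation
    harness with fivefold repeated splitting.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
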