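Package: synx
Title: Synergy Extrapolation for Unmeasured Muscle Excitations in
    EMG-Driven Musculoskeletal Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the excitation of an unmeasured muscle from synergies
    extracted from measured electromyography (EMG) by tracking inverse-dynamics
    joint moments with an EMG-driven Hill-type musculoskeletal model ("synergy
    extrapolation", SynX). Includes the full EMG processing chain (zero-phase
    filtering, five normalization schemes, gait-cycle time normalization),
    per-trial synergy analysis by PCA or alternating-least-squares NMF,
    rigid-tendon Hill-type forward moment prediction with first-order activation
    dynamics and electromechanical delay, simplified joint-moment-tracking model
    calibration, the 2 algorithms x 5 normalizations x 8 synergy-number
    methodological sweep, evaluation metrics (VAF, RMSE, Pearson r bands, MAE),
    and a seeded virtual-subject generator producing synergy-structured gait
    trials so every stage is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
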