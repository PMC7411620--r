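Package: affectfuse
Title: Multimodal Physiological Emotion Recognition with Modality-Level Fusion
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for recognizing four Russell-quadrant emotions
    (happy, angry, sad, relaxed) from wearable physiological recordings:
    four-channel EEG (TP9, AF7, AF8, TP10), galvanic skin response and
    photoplethysmography, all sampled at 256 Hz. Includes a seeded synthetic
    session generator with emotion-dependent signal structure, Savitzky-Golay
    smoothing, Welch band-power estimation, hemispheric asymmetry features
    (RASM, DASM, band-power correlation), electrodermal moment and entropy
    features, pulse-peak heart-rate and inter-beat-interval features,
    self-assessment-manikin quadrant labeling, k-nearest-neighbour
    classification under stratified cross-validation with modality-level
    fusion, and the full evaluation surface (accuracy, Cohen's kappa,
    sensitivity and specificity, precision, recall, F-score, and
    prior-relative nominal error statistics).
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
    class,
    withr,
    optparse
Config/testthat/edition: 3
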