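Package: affectlytics
Title: Affective Learning Analytics from Multimodal Biosignals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for affective learning analytics from wearable
    biosensors. Synchronizes and segments multi-rate biosignal streams
    (EEG at 256 Hz, heart rate at 1 Hz, electrodermal activity at 4 Hz)
    around annotated educational events, extracts EEG band metrics
    (alpha amplitude and the theta/beta power ratio via Welch spectral
    estimation with amplitude-threshold artifact rejection) and
    peripheral arousal metrics (mean heart rate, mean skin conductance),
    compares a baseline virtual-patient session against a mixed-reality
    session per participant and per group, counts directional metric
    shifts, and maps delta sign patterns to rule-based engagement and
    arousal labels. Includes a seeded synthetic-recording generator with
    known ground truth so the whole pipeline is testable without
    recording hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
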