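Package: gaitfog
Title: Freezing-of-Gait Detection from Binary Plantar-Pressure Insole Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting freezing of gait (FoG) in Parkinson's
    disease from bilateral smart-insole recordings in which six
    pressure-sensing units per foot emit binary on/off signals at 32 Hz.
    Implements gait-phase segmentation (single support, swing, double
    support) from the per-foot combined signal, per-user calibration of
    baseline phase durations, ratio-threshold FoG indices for long double
    support and continuous short swings, offline event extraction and an
    equivalent online onset detector, fuzzy-zone threshold training by
    maximising sensitivity plus specificity, event-level evaluation with
    correct/over/under-detection accounting, a packetized-streaming
    latency model with a cueing controller state machine, and a synthetic
    pathological-gait generator with labelled ground truth for end-to-end
    testing without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
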