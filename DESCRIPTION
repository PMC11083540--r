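Package: stspipe
Title: Multimodal Sit-to-Stand Analysis of Lumbar Load
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for integrated analysis of sit-to-stand (STS) movements
    recorded with surface electromyography of the erector spinae, a balance
    board measuring the center of pressure (COP), and a depth camera
    providing 3D joint coordinates. Implements the full processing chain:
    EMG envelope extraction (rectification, 5-30 Hz band-pass, moving
    average, min-max scaling), resampling of heterogeneous-rate streams to a
    common 1000 Hz clock, event-based inter-stream synchronization, stand-up
    epoch segmentation from pelvis and head height, missing-frame exclusion,
    per-epoch features (integrated EMG, maximum EMG, mean anterior-posterior
    COP, maximum trunk flexion angle), and the paired-comparison statistical
    battery with Benjamini-Hochberg correction. Ships a synthetic session
    generator with known ground truth so every stage can be validated
    without access to laboratory recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    pracma,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
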