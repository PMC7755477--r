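Package: transfercsp
Title: Task-Transfer Common Spatial Patterns for Motor-Imagery EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for two-class motor-imagery EEG decoding with scarce
    calibration data. Builds a full bank of common spatial pattern (CSP)
    filters from source-task recordings, transfers them to a new target
    task by Fisher-ratio scoring of log-variance band-power features, and
    classifies with an RBF support vector machine. Includes a synthetic
    session generator with planted ground truth (linear mixing of
    band-limited sources with lateralized event-related desynchronization),
    a standard preprocessing chain (linked-mastoid re-referencing, bad
    channel interpolation, zero-phase 8-30 Hz band-pass, epoching, baseline
    correction), EDF and tabular I/O, and an inverted cross-validation
    protocol with CSP and power-spectral-density baselines.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    signal,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
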