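Package: emdecho
Title: Atrial Electromechanical Dissociation Assessment from ECG and Tissue Doppler Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Non-invasive assessment of atrial electromechanical dissociation
    during atrial fibrillation. Extracts the atrial electrical activation rate
    from surface ECG after PCA-based QRS-T cancellation, the mechanical
    activation rate from tissue-Doppler velocity frame stacks via wall
    segmentation, pixel averaging and empirical-mode-decomposition denoising,
    and computes the electromechanical dissociation index with its 0.32 Hz
    classification threshold. Also implements dual-excitation ratiometric
    motion-artifact cancellation and voltage-calcium dissociation analysis for
    optical-mapping recordings, and a synthetic-data generator with known
    ground truth for every experimental scenario.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    signal,
    pracma,
    jsonlite,
    EBImage
Suggests:
    rhdf5,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
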