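Package: slecg
Title: Single-Lead ECG Classification via Teacher-Guided Feature Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for training and evaluating single-lead electrocardiogram (ECG)
    rhythm classifiers that recover part of the discriminative power of a full
    12-lead recording. A frozen 12-lead teacher network supervises a single-lead
    student in feature space: a transformer encoder maps single-lead features
    towards the teacher's 12-lead feature distribution, and a cross-attention
    module fuses reconstructed and original features before classification.
    Includes a multi-scale CNN-transformer feature extractor with omni-scale
    convolutions and squeeze-and-excitation gating, a reverse-mode automatic
    differentiation engine the networks train on, a synthetic multi-lead ECG
    generator with an engineered single-lead information deficit, the full
    preprocessing chain (Butterworth band-pass, z-score, FFT resampling,
    fixed-length padding, patient-level splits, class-balanced sampling),
    macro-averaged evaluation metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    yaml,
    jsonlite,
    withr,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
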