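Package: wmlr
Title: Wave-Masked Linear Reconstruction of 12-Lead ECGs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Reconstructs missing precordial ECG leads from a reduced lead
    set (I, II, V3) with a per-sample linear transform whose inputs are
    augmented by zero-masked P, QRS and T wave channels. Includes wave
    delineation on the reduced lead set, classical preprocessing (trimming,
    rational resampling, zero-phase denoising), metadata-criteria record
    selection, patient-wise k-fold evaluation with Pearson correlation and
    RMSE, paired t-test comparisons, reduced-scale LSTM and feed-forward
    committee baselines, a synthetic 12-lead ECG cohort generator with
    known fiducials and lead mixing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
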