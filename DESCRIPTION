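Package: bpnet
Title: Cuffless Blood Pressure Estimation from PPG with a 1D Squeeze U-Net
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for estimating systolic, diastolic and mean
    arterial blood pressure from a single-channel fingertip photoplethysmogram
    (PPG). Maps 256-sample PPG windows sampled at 125 Hz to arterial blood
    pressure (ABP)-like waveforms with a one-dimensional Squeeze U-net
    (SqueezeNet fire modules inside a U-net encoder-decoder), then reads
    systolic/diastolic pressures off the predicted waveform by peak detection.
    Includes a reproducible paired-waveform simulator, FIR bandpass
    preprocessing with cross-correlation phase matching, network training with
    Adam and early stopping, British Hypertension Society (BHS) and AAMI
    device-grading statistics, Bland-Altman analysis, hypertension-stage
    classification, and a real-time streaming inference loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
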