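Package: cuffbp
Title: Cuff-Less Blood Pressure Estimation from ECG and PPG with a Hybrid
    CNN-SVR Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Continuous, cuff-less estimation of systolic and diastolic blood
    pressure from paired electrocardiogram (ECG) and photoplethysmogram (PPG)
    waveforms sampled at 125 Hz. Implements the full hybrid pipeline: waveform
    record ingestion (CSV and WFDB), polynomial baseline-wander removal and
    Savitzky-Golay denoising, threshold-based R-peak detection, R-centered
    one-second beat segmentation, a five-block 1-D convolutional network
    trained as a feature extractor with half-mean-squared-error loss, and
    epsilon-insensitive support vector regression with a radial basis function
    kernel tuned by cross-validated grid search. Includes a synthetic
    cardiovascular waveform simulator (R-waves, pulse-transit-time-delayed PPG
    pulses, inverse PTT-to-BP coupling) so the whole pipeline can be trained
    and evaluated without access to clinical waveform databases, and an AAMI
    SP10 compliance report (mean absolute error, error standard deviation,
    cohort size).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    e1071,
    jsonlite,
    kernlab,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
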