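Package: ecgstack
Title: Multi-Channel Superposition Denoising for Weak Wearable ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for detecting weak electrocardiogram (ECG) signals with
    multi-electrode arrays by superposing (averaging) K simultaneously
    recorded channels, which suppresses unrelated channel noise by 1/sqrt(K).
    Provides a parametric synthetic multi-channel ECG generator with
    controllable morphology, noise and per-channel phase misalignment; the
    channel-averaging estimator and its theoretical signal-to-noise-ratio
    (SNR) gain; evaluation metrics (peak-to-peak QRS/noise SNR, R-peak
    detection, beat-wise heart-rate series and correlation, common-mode
    rejection ratio, input-referred noise, frequency response); a zero-phase
    IIR filter chain (powerline notches, band limiting) with steady-state
    edge handling; and a bit-exact codec for 26-byte acquisition-board
    packets carrying eight 24-bit ADC samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
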