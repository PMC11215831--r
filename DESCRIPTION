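Package: itcast
Title: Short-Term Epileptic Seizure Prediction from Two-Channel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-specific short-term prediction of epileptic seizures
    (detection of the brief pre-seizure Intervention-Time state) from two
    scalp EEG channels. The pipeline band-pass filters and detrends the
    signals, decomposes them into six Daubechies-4 wavelet detail signals
    per channel, tracks weak quasi-periodicities with a recursive
    least-squares autoregressive model followed by the first real-cepstrum
    coefficient per window, compares current (median-filter foreground) to
    background (exponentially forgotten median) energy across the two
    channels, and learns per-output patient-specific thresholds on the
    positive envelope of the averaged ratio series. Alarms are raised by a
    majority vote of the accepted outputs within fixed seizure-occurrence
    windows. A generative model of adult epileptic EEG (colored-noise
    background plus shaped quasi-periodic seizure components) is included so
    the full pipeline can be trained and evaluated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
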