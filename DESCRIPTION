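Package: sdareeg
Title: Change-Point Detection of Oscillatory Bursts in EEG with Discounted
    Autoregressive Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Online detection of short narrowband oscillatory bursts (alpha
    spindles) in EEG time series using sequentially estimated discounted
    autoregressive (DAR) models. The sequential discounted AR (SDAR) recursion
    tracks time-varying AR coefficients with exponential forgetting and scores
    each sample by its squared one-step prediction error; smoothed loss traces
    are thresholded, combined across channels by voting, and post-processed
    into event intervals. Includes weighted F-measure threshold optimization,
    fuzzy-window labeled-interval comparison metrics (precision, sensitivity,
    specificity, hit rate, temporal error), an amplitude-spectral-density FWHM
    baseline detector, and seeded synthetic-data generators for AR change-point
    processes and multichannel spindle EEG.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
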