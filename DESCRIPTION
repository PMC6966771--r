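Package: mtenet
Title: Directed Network Inference by Multivariate Transfer Entropy and
    Granger Causality
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimation of directed (effective) networks from multichannel
    time series by bivariate transfer entropy, multivariate (conditional)
    transfer entropy with greedy relevant-source selection, and multivariate
    Granger causality with AIC order selection. Includes plug-in and Gaussian
    transfer-entropy estimators with circular-shift surrogate significance
    testing, a simulation benchmark over linear and non-linear coupled
    networks under controlled signal-to-noise ratios, confusion-matrix and
    adjacency-bias scoring, a P300 oddball EEG preprocessing and group
    comparison pipeline, and a synthetic two-group EEG cohort generator with
    planted, group-differentiated frontal-to-parietal coupling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
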