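Package: remalpha
Title: Unsupervised REM Sleep Detection from Intracranial EEG by Multitaper
    Alpha-Rhythm Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Separates rapid-eye-movement (REM) sleep from wakefulness in
    multichannel intracranial EEG recordings that lack the EOG and EMG
    channels conventional sleep staging relies on. Thirty-second epochs are
    summarised by complex multitaper eigencoefficients of the alpha rhythm
    (10 Hz, 2 Hz half-bandwidth, discrete prolate spheroidal tapers), the
    epochs are grouped by a likelihood-based K-means over the complex
    feature matrices with an approximate-AIC sweep over the number of
    clusters, and the REM cluster is identified as the cluster with the
    lowest median per-contact alpha-power rank. Includes EDF input/output,
    zero-phase power-line notch filtering, a synthetic night generator with
    a known hypnogram for validation, hold-out split evaluation, and a
    matched-power alpha-threshold baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
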