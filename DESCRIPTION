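Package: touchcode
Title: Decoding Social Touch Expressions from Single-Afferent Spike Trains
Version: 0.1.0
Authors@R:
    person("Touchcode", "Developers", email = "touchcode@example.org",
           role = c("aut", "cre"))
Description: Tools for asking whether single mechanoreceptive afferents can
    discriminate human-delivered social-touch expressions from their spike
    trains. Provides a spike-train data model at 1 ms resolution with
    instantaneous-firing-frequency (IFF) computation, aggregate rate-coding
    features, a temporal-coding classifier (a small 1-D convolutional network
    on binary spike trains) and a rate-coding classifier (linear
    support-vector machine on five firing features) under repeated stratified
    cross-validation, sliding-window identification of the most informative
    spike-train segment, saturation window-length estimation from
    fourth-order polynomial accuracy curves, and spike-timing jitter
    sensitivity analysis. A synthetic generator produces labeled spike trains
    with the contact rhythms of six standardized touch expressions passed
    through afferent-subtype response models, so the full pipeline is
    testable without microneurography recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
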