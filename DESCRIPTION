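Package: actifrag
Title: Reliability of Rest-Activity Rhythm Fragmentation Metrics Under
    Accelerometer Non-Wear
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes rest-activity rhythm (RAR) fragmentation metrics
    (interdaily stability, intradaily variability, day and night
    transition probabilities from bout durations, the detrended
    fluctuation analysis scaling exponent alpha, and the activity
    balance index) from 60-second epoch wrist-accelerometer series, and
    quantifies their reliability under reduced wear protocols.
    Artificial non-wear blocks are inserted under three valid-day
    scenarios, handled by omission or epoch-level mean imputation, and
    each batch is compared against complete seven-day data with
    intraclass correlation and mean absolute percent error to derive
    per-metric minimum-valid-day recommendations. A synthetic-cohort
    generator with known two-state bout dynamics and canonical noise
    series with known scaling exponents support validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
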