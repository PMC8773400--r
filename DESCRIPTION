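Package: cardtrace
Title: Concordance of Bluetooth Proximity Cards and Interview-Based Contact Tracing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate Bluetooth Low Energy (BLE) proximity cards as a
    contact-tracing instrument against traditional interview-based case
    investigation. Provides a synthetic-data generator for dyadic contact
    events, RSSI streams under a log-distance path-loss model, wear
    compliance and interview recall; a card-data pipeline that discretises
    RSSI into proximity classes and aggregates 15-second scans up to daily
    dyad records; directed-network reciprocity statistics (dyad census,
    traditional reciprocity r, the Garlaschelli-Loffredo density-adjusted
    measure with jackknife standard errors); grouped-binomial logistic
    models of reciprocity trends with likelihood-ratio tests; and
    confusion-matrix concordance of card-detected versus self-reported
    contact events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    lubridate,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
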