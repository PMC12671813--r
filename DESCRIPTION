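Package: skipjacktag
Title: Archival-Tag Movement and Thermal Physiology Analysis for Skipjack Tuna
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing archival-tag (depth, internal and external
    temperature, light) and plastic-dart-tag records of skipjack tuna
    released at the northern limit of their range. Implements light-based
    geolocation (template fit of day length and local noon) refined by
    matching tag-measured sea-surface temperature against a gridded field
    in an unscented Kalman smoother, daily movement metrics and
    spawning-potential versus residence classification at the 25 degree N
    boundary, detection and characterisation of extraordinary body
    temperature events above 31 degrees C, group-average agglomerative
    clustering of daily thermal traits, gonadal maturity indices and
    histology-based staging, and decadal mark-recapture summaries. A
    synthetic tag-data generator reproduces the statistical structure of
    the study system so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    geosphere,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
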