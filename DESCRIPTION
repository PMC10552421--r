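Package: msms
Title: Multi-Scale Movement Syndromes from GPS Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A trajectory-analysis toolkit for high-resolution GPS telemetry
    implementing a multi-scale movement syndrome framework. Reads
    Movebank-style tracking tables, cleans and reconstructs tracks (burst
    selection, altitude/boundary/speed outlier screening, negative-binomial
    error interpolation of inactivity gaps), computes movement metrics at the
    step scale (Gamma step lengths, von Mises turn angles), the daily-path
    scale (distance, straightness, sinuosity, behavioral time budgets), and
    the life-history-phase scale (turn-angle correlation, residence time,
    time-to-return, kernel home ranges and utilization-distribution overlap,
    net squared displacement); segments behavior into cluster,
    area-restricted search and travel via first-passage times with
    correlated-velocity-model imputation at path edges; and compares
    individuals and species through nested variance partitioning and
    standardized principal component syndrome spaces. Includes a multi-state
    correlated random walk simulator with burst-structured observation and
    GPS error for fully synthetic studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    fitdistrplus,
    geosphere,
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
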