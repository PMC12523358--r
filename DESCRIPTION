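Package: grazeproxy
Title: Grazing Intensity from Dung Proxies and Repeated Aerial Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying livestock grazing intensity in fenced
    household pastures from repeated drone surveys. Implements an adapted
    kernel density estimator that converts hourly herd snapshots into
    grazing-intensity rasters in yak-hours per square metre (triangular
    kernel, monitoring-day adjustment, cumulative aggregation), UAV
    footprint geometry and waypoint route design, a seeded virtual-pasture
    simulator (campsite-centred herd movement, dung deposition and decay,
    riverbed washout, flight-height-dependent detection), and the
    calibration stage relating observed dung density to cumulative grazing
    intensity across accumulation windows (OLS fits, R-squared trend,
    flight-height accuracy comparison, inverse prediction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    car
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
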