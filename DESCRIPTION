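Package: aqilag
Title: Distributed-Lag Analysis of Air Quality Index Effects on Daily Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for time-series analysis of composite Air Quality Index (AQI)
    effects on daily cardiovascular and cerebrovascular death counts. Computes
    per-pollutant sub-indices and the composite AQI by piecewise-linear
    interpolation over national breakpoint tables, builds distributed lag
    nonlinear model (DLNM) cross-bases from natural cubic splines, fits Poisson
    log-linear models, converts fitted coefficients into single-day and
    cumulative lag relative risks with confidence intervals, and quantifies
    additive and multiplicative interaction between AQI and meteorological
    factors (IRR, RERI, AP) with delta-method intervals. Includes a seeded
    synthetic-data generator with a known exposure-lag-response surface so the
    whole pipeline is testable without access to mortality registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    splines,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
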