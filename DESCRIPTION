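Package: toaesize
Title: Body-Size Response of Benthic Shell Communities to Seawater
    Temperature Across a Hyperthermal Event
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking shell size of fossil bivalve-brachiopod
    communities to oxygen-isotope derived seawater temperature across the
    Toarcian Oceanic Anoxic Event (Early Jurassic). Provides specimen and
    isotope table I/O and validation, log2 geometric-mean shell-size
    computation with hierarchical imputation of unmeasured specimens,
    per-sample community trajectories (mean size, interquartile range,
    percent of larger-sized individuals), carbonate palaeothermometry with
    trace-element diagenesis screening, and a lag-aware correlation
    procedure combining trend and autocorrelation diagnostics, generalized
    differencing, automatic ARIMA order selection and generalized least
    squares regression with ARMA-structured errors. A synthetic-data
    generator reproduces the statistical structure the analysis assumes so
    that every stage is testable, including type-I error and parameter
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    nlme,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
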