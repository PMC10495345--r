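Package: fluxqaqc
Title: Quality Assurance and Quality Control for Eddy-Covariance Flux-Met Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening half-hourly and hourly eddy-covariance
    flux-meteorology ("flux-met") records before publication. Reads and
    writes the comma-delimited FP-In exchange format (paired
    YYYYMMDDHHMM start/end timestamps, -9999 missing sentinel,
    controlled variable vocabulary), performs a format compliance pass
    with a single automatic correction attempt, and runs six data
    quality checks: timestamp alignment against top-of-atmosphere
    potential radiation, physical range and variability screening,
    multivariate consistency, diurnal-seasonal pattern checks, friction
    velocity (USTAR) filtering detection, and variable coverage. Also
    includes a synthetic flux-met site generator with declarative fault
    injection for end-to-end testing, and rectified Morlet wavelet
    power spectra for characterising multi-year flux records.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
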