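Package: rtfit
Title: Dose-Dependent Retarded Transient Function Modelling of Signalling
    Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Phenomenological modelling of time- and dose-dependent cellular
    signalling responses with the retarded transient function (RTF): a
    sustained and a transient exponential component evaluated on a
    non-linearly retarded time axis, with Hill-type dose dependencies of the
    dynamic parameters and multiplicative fold-changes between biological
    conditions.  Provides multi-start maximum-likelihood fitting with
    Latin-hypercube start sampling and waterfall diagnostics,
    profile-likelihood confidence intervals, likelihood-ratio testing of
    condition fold-changes, backward-elimination model reduction, a tidy
    CSV reader/writer for long-format time-course tables, and a synthetic
    data generator emulating dose-response ELISA designs.
License: MIT
Encoding: UTF-8
Imports:
    lhs,
    jsonlite,
    stats,
    graphics,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
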