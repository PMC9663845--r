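Package: numadapt
Title: Behavioral and ERP Analysis of Numerosity Adaptation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing numerosity-adaptation experiments that combine
    verbal numerosity estimation with event-related potentials (ERPs). Provides
    a synthetic-data generator for behavioral estimate tables and epoched
    multi-channel EEG (parametric ERP components on 1/f + alpha + white noise),
    an ERP preprocessing chain (FIR band-pass, downsampling, spherical-spline
    bad-channel interpolation, average reference, epoching with baseline
    correction, peak-to-peak epoch rejection), behavioral statistics
    (quartile-based response pruning, repeated-measures ANOVAs with
    Tukey-Kramer post-hocs and effect sizes, noncentral-F a-priori power
    analysis), and time-point-wise paired bootstrap statistics with
    Benjamini-Hochberg FDR and temporal-persistence thresholding used to
    isolate perceived-numerosity signatures in posterior ERP components.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
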