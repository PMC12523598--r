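Package: bracketqc
Title: Risk-Based Multistage Statistical Quality Control Design for
    Clinical Laboratories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing risk-based, multistage bracketed
    statistical quality control (SQC) strategies in high-throughput
    clinical laboratories. Computes sigma metrics from internal
    quality control summaries and allowable total error
    specifications, evaluates Westgard control rules and their power
    functions (probability of error detection and false rejection),
    implements the expected number of unreliable final patient
    results E(Nuf) risk model with Max E(Nuf)-bounded run sizes and
    the sigma-metric run size nomogram, designs startup/monitor
    multistage QC plans from sigma and workload, and consolidates
    plans across analyzers into general and individualized sets. A
    bracketed patient-flow simulator provides an empirical check of
    the analytic risk model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
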