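Package: panelval
Title: Analytical Validity Assessment for Targeted Gene-Panel Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to assess the analytical validity of targeted
    next-generation-sequencing gene panels against orthogonal truth.
    Implements per-region and panel-wide depth-of-coverage summaries,
    a population-frequency and positional variant-filtering cascade,
    variant-call confidence triage by sequencing depth and allele
    balance, concordance analysis (sensitivity, specificity, and
    per-gene false discovery rate in two filtering modes) against
    Sanger confirmation and prior clinical gene screening, exact
    inference for 2x2 ancestry contingency tables with a
    conditional-MLE odds ratio, and a fully seeded synthetic
    panel-screening data generator so that every pipeline stage is
    testable without raw sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
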