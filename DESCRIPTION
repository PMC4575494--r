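Package: strlr
Title: Semi-Continuous Likelihood Ratios for Forensic STR Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes likelihood ratios for complex (low-template, mixed,
    partial) forensic short tandem repeat (STR) profiles under a
    semi-continuous probabilistic genotyping model: explicit allelic
    drop-out and drop-in probabilities, a coancestry (theta) correction
    applied at the allelic level via conditional Balding-Nichols sampling,
    assumed-contributor allele masking, kinship hypotheses expressed as
    identity-by-descent probabilities, and summation over up to four
    unknown contributors using a dynamic-programming algorithm checked
    against exhaustive enumeration. Includes readers and writers for
    genetic-analyzer CSV exports and allele-frequency tables, a
    logistic-regression drop-out probability estimator, a seeded synthetic
    data generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
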