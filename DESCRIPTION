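Package: pcbtox
Title: Equilibrium Partitioning and Cytotoxicity Analysis for
    Lower-Chlorinated PCBs and Their Metabolites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models the equilibrium distribution of lower-chlorinated
    polychlorinated biphenyls (PCBs) and their hydroxylated and sulfated
    metabolites across the compartments of an in vitro exposure system
    (culture medium, headspace air, and cellular lipid, protein and water)
    from polyparameter linear free-energy relationships and
    temperature-corrected Henry's law constants.  Analyses MTT and LDH
    plate-reader data by four-parameter logistic regression with
    range-censored IC50 reporting and exact nonparametric per-concentration
    group comparisons.  A seeded synthetic-data generator reproduces the
    plate layout and replicate structure of such studies so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
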