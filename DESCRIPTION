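Package: prstrial
Title: Polygenic Scores as Moderators of Intervention Response in
    Longitudinal Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to test whether polygenic risk scores (PRS) and
    gene-set variant burden moderate response to a behavioural
    intervention in a two-arm longitudinal trial. Covers genotype
    quality control with an exact Hardy-Weinberg test, clump-and-
    threshold PRS construction from GWAS summary statistics, linear
    mixed models with PRS-by-time-by-intervention interactions and
    marginal/conditional R-squared decomposition, cluster-bootstrap
    power estimation, and a competitive gene-set association test on
    outcome change scores. Includes a synthetic-data generator with
    linkage-disequilibrium block structure and configurable
    interaction effects so the whole pipeline is testable without
    access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
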