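Package: gxekit
Title: Genotype-by-Environment Interaction Encoding for GWAS and Genomic
    Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Expands a numeric genotype matrix by a Kronecker product with an
    environment design matrix so that additive and environment-interactive
    marker effects occupy separate columns, and runs the surrounding
    multi-environment workflow: correlated phenotype simulation with
    controlled heritability and genetic correlation, mixed-linear-model
    association scans with a kinship built from the expanded genotype,
    power and false-positive-rate curves against simulation truth, and
    genomic prediction (GBLUP and Bayesian whole-genome regression) under
    cross-validation with single- or double-environment missing-phenotype
    schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
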