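Package: lancpath
Title: Two-Stage SKAT-Lancaster Pathway Analysis for Sequencing Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Pathway (gene-set) association testing for sequencing studies by a
    two-stage combined p-value procedure. Stage one summarises rare-variant
    effects within each gene with the sequence kernel association test (SKAT),
    a variance-component score test whose null is a mixture of one-degree
    chi-squares evaluated by characteristic-function inversion. Stage two
    combines gene-level p-values within a pathway by the Lancaster procedure
    (weighted inverse chi-square transforms), with a Satterthwaite scaled
    chi-square null that corrects for correlation among genes, a competitive
    gene-shuffling permutation variant, Bahadur efficiency slope calculators
    for the main weighted combined p-value methods (Fisher, regular and
    weighted Z, Good, Lancaster), and a synthetic-data engine for calibration
    and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
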