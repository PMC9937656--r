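Package: kinsub
Title: Kinase Substrate Discovery from SILAC Phosphoproteomics and In Vitro Kinase Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline that turns quantitative SILAC phosphoproteomics
    time courses (kinase inhibitor versus vehicle) and on-beads in vitro kinase
    assay (OBIKA) measurements into a ranked, classified set of direct kinase
    target phosphosites. Implements localization-probability and replicate
    filtering, protein-level normalization, Perseus-style down-shifted normal
    and maximum-likelihood missing-value imputation, per-site random-effects
    effect estimation with inhibitor-contrast t-tests and Benjamini-Hochberg
    FDR, class I/II site classification, intersection of the in vivo and in
    vitro branches into a bona fide target set, kinetic-profile hierarchical
    clustering, and phosphosite sequence-motif enrichment. Includes a
    synthetic-data generator with known ground truth so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
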