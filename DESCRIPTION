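Package: cypred
Title: Prediction of the Cytochrome P450 Isoform Metabolizing a Drug Molecule
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for predicting which of the five major cytochrome P450
    isoforms (CYP3A4, CYP2D6, CYP1A2, CYP2C9, CYP2C19) metabolizes a drug
    molecule. Computes 1D/2D molecular descriptors from SMILES or SDF input,
    prunes them with a four-rule filter cascade (missingness, sparsity,
    pairwise correlation, multicollinearity), selects a compact subset by
    genetic-algorithm or greedy stepwise wrapper search, fits one-vs-rest
    support vector machine classifiers with per-isoform decision thresholds
    calibrated to maximize the Matthews correlation coefficient, and
    evaluates single-label and multi-label predictions under five-fold and
    leave-one-out cross-validation. Includes a synthetic descriptor-table
    generator for end-to-end testing and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    ChemmineR,
    e1071,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
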