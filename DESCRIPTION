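Package: qsrrga
Title: Consensus GA-PLS Modelling of Chromatographic Retention from
    Quantum-Chemical Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quantitative structure-retention relationship (QSRR) modelling
    of chromatographic retention times from mechanistic quantum-chemical
    molecular descriptors. Computes antioxidant-mechanism (HAT/SPLET) and
    conceptual-DFT reactivity descriptors from quantum-chemistry summary
    tables, splits datasets with the Kennard-Stone algorithm, fits SIMPLS
    partial least squares models with leave-one-out cross-validation,
    selects descriptors with a binary genetic algorithm, builds consensus
    models from descriptor occurrence over repeated runs, and validates
    them with external test sets, cross-validated ANOVA, and Williams-plot
    applicability-domain diagnostics. Includes a synthetic-data generator
    emulating the statistical structure of flavonoid retention datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    Matrix,
    Rcpp,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
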