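Package: sctyper
Title: Automated Immune Cell-Type Annotation and Cross-Tissue Composition
    Statistics for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates cells in single-cell RNA-seq count matrices using
    L2-regularized multinomial logistic regression trained by mini-batch
    stochastic gradient descent in two rounds: a first fit on all genes,
    classifier-driven selection of each cell type's top-weighted marker
    genes, and a second fit restricted to the union of those markers.
    Supports a two-level (fine/coarse) cell-type label hierarchy,
    iterative model updating with newly curated labels, per-class
    precision/recall/F1 evaluation with learning curves, and cross-tissue
    composition analysis via donor-stratified Poisson regression with
    Benjamini-Hochberg correction. Includes a seeded negative-binomial
    synthetic dataset generator with planted marker programs, tissue and
    donor structure, so every component is testable without external data,
    plus a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
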