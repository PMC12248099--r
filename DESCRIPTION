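Package: fabgene
Title: Embedding-Informed Frequentist and Bayesian Hypothesis Tests for
    Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Frequentist and Bayesian (FAB) hypothesis tests that use the
    principal subspace of a gene-embedding matrix as a source of prior
    information while retaining exact frequentist type I error control.
    Implements an embedding-projected two-sample test for high-dimensional
    means (oracle, limiting, and practical Hotelling-type variants with
    naive and split-sample whitening), a FAB F-test for linear hypotheses
    relating a response profile to gene expression (Monte Carlo and
    limiting forms), and a panel of FAB t-tests whose prior moments are
    obtained by Gaussian conditioning on leave-one-out difference scores.
    Also provides the subspace-alignment diagnostic with its Haar-random
    null band, a simulation harness for type I error and power studies,
    Benjamini-Hochberg adjustment utilities, and delimited-text readers
    for embedding and profile matrices.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
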