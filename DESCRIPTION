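Package: modconn
Title: Modular Connectivity Factorization for Stacks of Connectivity Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes the variability of a collection of symmetric
    connectivity matrices (across subjects or time windows) into
    interpretable modular components. Implements modular connectivity
    factorization (MCF), a constrained principal component analysis in
    which each eigenconnectivity matrix is factorized as B = W G W' with
    disjoint nonnegative module weight vectors W and a small module-level
    eigenconnectivity matrix G, together with the unconstrained PCA
    eigenconnectivity analysis and the orthogonal connectivity
    factorization (OCF) baseline, a stepwise post-hoc factorizer, multi-
    component deflation with adjusted explained variance, simulation
    generators with known ground truth, and a recovery benchmark
    comparing the methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
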