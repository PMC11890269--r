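Package: cdimpute
Title: Constrained Diffusion Imputation for Single-Cell RNA-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Imputes dropout zeros in single-cell RNA-seq count matrices by
    Markov diffusion smoothing on an adaptive Gaussian k-nearest-neighbour
    graph, with the smoothing weights of every gene in every cell constrained
    by the average expression of that cell's most similar neighbours: highly
    expressed genes diffuse less, which limits over-smoothing. Observed
    non-zero counts are preserved exactly; only zeros are replaced. Includes a
    cluster-structured negative-binomial simulator with expression-dependent
    dropout, evaluation utilities (ARI, NMI, purity, expression-dropout
    correlation, correlation to a reference profile), readers and writers for
    dense delimited and MatrixMarket expression matrices, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    igraph
Config/testthat/edition: 3
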