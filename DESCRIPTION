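Package: cask
Title: Estimating the Number of Cell Types in Single-Cell Chromatin Accessibility Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ensemble estimation of the number of cell types in single-cell
    chromatin accessibility (scATAC-seq) peak-by-cell count matrices. Combines
    a within-cluster sum-of-squares elbow criterion, the Davies-Bouldin index,
    and a silhouette criterion over graph-based (Louvain/Leiden) clusterings,
    with a weighted-bias resolution search that accelerates finding a
    partition of a given size. Includes TF-IDF/PCA preprocessing, readers for
    MatrixMarket/BED/barcode triples and AnnData (.h5ad) containers, and a
    synthetic-data generator with configurable cell-type structure, imbalance,
    sparsity and dropout.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    irlba,
    RANN,
    rhdf5,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    cluster,
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
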