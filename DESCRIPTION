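Package: coocclust
Title: Co-Occurrence Clustering of Single-Cell RNA-Seq Dropout Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Clusters single cells from the binary zero/non-zero (dropout)
    pattern of scRNA-seq count matrices. Counts are binarized without
    normalization or imputation; gene "pathways" are detected as Louvain
    communities of a Jaccard-reweighted gene-gene graph built from a signed
    chi-square co-occurrence score with a permutation-derived edge threshold;
    cells are embedded by per-pathway percentage of detection, clustered on a
    Jaccard-weighted k-nearest-neighbour graph, and cluster pairs lacking a
    prominently differential pathway (SNR, mean difference, mean ratio
    criteria) are merged. The procedure is applied divisively so that leaves
    of the resulting hierarchy are the reported cell types. Includes a
    planted-model simulator for binary dropout matrices, partition scoring
    (Rand and adjusted Rand index), hypergeometric gene-set enrichment, 10X
    MTX and dense CSV/TSV readers, and GMT import/export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
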