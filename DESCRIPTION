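Package: gpdrp
Title: Multimodal Graph Neural Network Regression of Drug Response from
    Molecular Graphs and Pathway Activity Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits a multimodal regressor of drug sensitivity (log
    half-maximal inhibitory concentration, LN IC50) for drug and cell-line
    pairs. Drugs are encoded as attributed molecular graphs built from
    SMILES with a five-block binary atom featurization and passed through
    one of four graph neural network encoders (graph convolution, graph
    attention, graph isomorphism, or a hybrid graph-transformer/graph
    isomorphism stack with Laplacian positional encodings); cell lines are
    encoded from min-max normalized pathway activity score vectors by a
    dense network. The two 128-dimensional embeddings are fused by a fully
    connected head that predicts the response on a (0,1) scale. Includes
    cell-line-grouped data splitting, the response scaling transform and
    its inverse, gene-set (GMT) handling, a synthetic benchmark generator
    with planted signal, and downstream analyses: drug ranking by median
    predicted response, hierarchical clustering of prediction matrices,
    and per-cluster pathway-score summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    pheatmap,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
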