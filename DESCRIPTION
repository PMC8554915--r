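Package: gfae
Title: Graph Feature Auto-Encoders for Predicting Unobserved Node Features on Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns low-dimensional embeddings of molecular interaction networks
    with a graph auto-encoder (GCN encoder, inner-product decoder) and predicts
    unobserved node features -- gene expression values -- with end-to-end
    message-passing neural networks trained under masked mean squared error.
    Implements four message-passing convolution layers (message-passing GCN,
    GraphSAGE with closed-neighbourhood mean pooling, GraphConv, and
    FeatGraphConv, a layer tailored to node-feature reconstruction), feature-only
    baselines (linear regression, random forest, multilayer perceptron), two
    masking protocols for train/test separation of expression values, K-fold
    cross-validated experiment drivers, and a synthetic-data generator producing
    Erdos-Renyi graphs with graph-smooth feature matrices so that every stage is
    testable without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    randomForest,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
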