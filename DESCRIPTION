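Package: phylofuse
Title: Phylogeny-Aware OTU Embeddings Fused with Abundance Features for
    Microbiome Analysis
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds phylogeny-aware OTU embeddings by principal component
    analysis of the patristic distance matrix of a rooted phylogenetic
    tree, and fuses them with abundance information in two ways: an
    unsupervised pipeline (robust Aitchison PCA of the abundance table,
    presence-based summation pooling of OTU embeddings, feature
    concatenation, PERMANOVA / K-means / KNN evaluation) and a supervised
    dual-tower neural network (a linear abundance tower and a 1D
    convolutional tower over tree-ordered OTU embeddings, fused by
    element-wise multiplication). Includes binary-classification and
    regression metrics, 68:12:20 and leave-one-dataset-out split
    utilities, and a Gaussian-copula (NorTA) simulator of correlated
    zero-inflated OTU counts with phylogenetically clustered
    outcome-associated taxa.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vegan
Config/testthat/edition: 3
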