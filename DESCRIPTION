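Package: netcbi
Title: Similarity-Based Inference of miRNA-Disease Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts associations between microRNAs and disease phenotypes
    on a bipartite network using three similarity-based scoring schemes:
    miRNA-based similarity inference (MBSI), phenotype-based similarity
    inference (PBSI), and network-consistency-based inference (NetCBI),
    which couples graph-Laplacian relevance propagation on the miRNA and
    phenotype similarity networks through a Pearson correlation score.
    Includes leave-one-out cross-validation with ROC/AUC evaluation,
    nested cross-validation for smoothing-parameter selection, a
    block-structured synthetic data generator with degree-preserving
    null models, and a command-line interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
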