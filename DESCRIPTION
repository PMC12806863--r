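Package: grncausal
Title: Causal Gene Regulatory Network Inference from Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers directed transcription-factor regulatory networks from
    gene expression matrices by combining graph-based gene representation
    learning with pairwise additive-noise-model causal discovery. Builds
    linear (Pearson) and nonlinear (mutual information) co-expression
    networks, learns gene embeddings with a two-layer mean-aggregating
    graph neural network trained on link prediction, scores every
    admissible regulator-target pair by the asymmetry of Gaussian-process
    regression residual independence (HSIC), and ensembles the two
    pipelines by weighted Borda voting. Ships DREAM-style evaluation
    (AUROC/AUPR with sampling-and-filling for truncated lists, a
    random-network confidence score, early precision ratio), a synthetic
    network-and-expression generator for end-to-end validation, and a
    stage-wise monotonicity screen for ranking driver transcription
    factors across ordered disease stages.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    mgcv,
    jsonlite
Config/testthat/edition: 3
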