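Package: mgcna
Title: Multi-Branch Graph Convolutional Networks with Separable Attention for EEG Seizure Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects epileptic seizures in multichannel scalp EEG with a
    multi-branch graph convolutional network fused by separable multi-head
    self-attention (MGCNA). Each EEG channel is a graph node; three parallel
    graph views drive three unshared GCN branches: a spatial-distance graph
    built from a Gaussian kernel on bipolar-derivation midpoints, a functional
    connectivity graph built from thresholded Pearson correlation, and a
    trainable adjacency constrained by normalization and rectification.
    Includes a synthetic EEG generator emulating 22-channel, 256 Hz pediatric
    recordings with annotated seizures, EDF input/output, Butterworth band-pass
    preprocessing, windowed segmentation with class rebalancing, patient-specific
    (stratified 5-fold) and patient-independent (leave-one-subject-out)
    evaluation protocols, confusion-matrix and rank-based AUC metrics, and a
    command-line interface. The network forward and backward passes and the
    Adam optimizer are implemented directly on dense linear algebra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
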