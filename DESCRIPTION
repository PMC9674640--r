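Package: motifembed
Title: Behavioral Motif Segmentation from Pose Estimation via Variational
    Recurrent Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised segmentation of animal behavior from pose-estimation
    time series. Egocentrically aligned marker trajectories are embedded into a
    low-dimensional latent space by a variational autoencoder built from
    bidirectional gated recurrent units, with a second decoder that forecasts
    the future of each trajectory window to regularize the embedding. The
    latent series is segmented into discrete behavioral motifs by a
    Gaussian-emission hidden Markov model (or k-means), motif transition
    matrices are estimated, motifs are merged into a hierarchical binary tree
    whose cuts yield behavioral communities, and segmentations are scored
    against reference annotations with Purity, Normalized Mutual Information
    and Homogeneity. A synthetic pose simulator with planted Markov-switching
    regimes makes the full pipeline testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    cluster,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
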