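Package: netdict
Title: Network Dictionary Learning, Reconstruction and Denoising with Latent Motifs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns low-rank mesoscale structure of undirected networks as a
    small dictionary of k-node weighted "latent motifs" by online nonnegative
    matrix factorization over adjacency patches induced by uniformly sampled
    k-paths. The learned dictionary supports weighted network reconstruction
    by nonnegative patch coding and per-pair averaging, with an explicit bound
    relating the weighted Jaccard reconstruction distance to the mean patch
    approximation error. Includes exact dynamic-programming k-walk/k-path
    samplers, random-graph generators (Erdos-Renyi, Watts-Strogatz,
    Barabasi-Albert, stochastic block model), edge corruption models with
    ground-truth labels, classical link-prediction baselines, and ROC/AUC
    evaluation for anomalous-edge detection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
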