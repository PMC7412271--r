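Package: mklselect
Title: Information-Source Selection with Multiple Kernel Learning and
    Locally Scaled Gaussian Kernels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Objective selection of relevant information sources (named blocks
    of features such as EEG electrodes or MRI sequences) in binary
    classification. Each source is represented by a Gaussian kernel whose
    per-sample bandwidths are set by local scaling (distance to the K-th
    nearest neighbour); the kernels are fused by an lp-norm penalized
    multiple-kernel-learning support vector machine whose trained kernel
    weights rank the sources. Includes three algorithms for assigning
    local-scaling bandwidths to unseen samples at prediction time, particle
    swarm optimization of the hyperparameters against a cross-validated
    geometric-mean objective, sequential source elimination curves, and a
    Fisher-score feature-selection baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    kernlab,
    jsonlite,
    yaml,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
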