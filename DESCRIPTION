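Package: slrprune
Title: Sparse Low-Rank Pruning of Fall-Detection Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compresses the fully-connected layers of vision-based fall
    detection networks with the sparse low-rank (SLR) method: the weight
    matrix of a dense layer is factorised by singular value decomposition,
    truncated to a reduction rank k, and each retained singular vector is
    additionally sparsified to a target density by absolute magnitude.
    Ships two reference backbones (a 2D-CNN over stacked video frames and a
    CNN-LSTM over frame sequences), a deterministic synthetic fall/ADL
    frame-sequence generator, a small pure-R training engine (Adadelta,
    backpropagation), stratified k-fold evaluation with micro/macro metrics,
    parameter-accounting and rank-sweep reports, and a pruned-model
    container with a JSON manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    png,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
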