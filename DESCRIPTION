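Package: netimage
Title: Brain Network Classification via Node-Embedding Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Builds phase-lag-index (PLI) functional connectivity networks from
    multichannel electrophysiology recordings, embeds the network nodes with
    weighted random walks and a skip-gram model, renders each network as a
    small multi-channel 2D-histogram image via PCA-aligned node features, and
    classifies the images with a compact LeNet-style convolutional neural
    network under k-fold cross-validation.  A synthetic-data module generates
    coupled-oscillator recordings, modular graphs and labeled two-class
    cohorts so that every pipeline stage can be exercised without clinical
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    tibble,
    ggplot2,
    generics,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
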