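Package: spotsparse
Title: Sparse Cell-Type Deconvolution for Cellular-Resolution Spatial
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deconvolves the cell-type composition of cellular-resolution
    spatial transcriptomics spots (Stereo-seq, Slide-seqV2, Pixel-seq style
    data) with a variational encoder-decoder trained on a negative binomial
    count model. Cell-type expression signatures and gene dispersions are
    estimated from a labelled single-cell RNA-seq reference by maximum
    likelihood; pseudo-spots pooled from reference cells with known
    proportions provide a supervised training signal; a sparsemax output
    layer yields exactly sparse per-spot compositions. Includes readers and
    writers for the common matrix formats, a synthetic-data generator with
    known ground truth, evaluation metrics (marker-gene Spearman
    correlation, Moran's I, Jensen-Shannon distance) and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    ggplot2,
    methods,
    optparse,
    stats,
    tibble,
    utils,
    withr
Suggests:
    ape,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
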