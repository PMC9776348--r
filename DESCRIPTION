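Package: ssmseg
Title: Self-Similarity-Matrix Segmentation of Uni- and Multichannel Biosignals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Unsupervised information retrieval from uni- and multidimensional
    biosignal time series via a feature-based self-similarity matrix (SSM).
    A sliding window extracts statistical, temporal and spectral features per
    channel; the doubly normalized feature matrix yields a cosine SSM.
    Change points are detected by correlating a Gaussian-tapered checkerboard
    kernel along the SSM diagonal (novelty function), period starts by valleys
    of the column-wise similarity function, and segments are compared and
    clustered through their similarity profiles. Includes tolerance-zone
    precision/recall/F1 evaluation, a labelled synthetic-signal generator for
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
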