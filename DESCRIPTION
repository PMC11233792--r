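Package: scsmap
Title: Sharpened Cosine Similarity Classification of Hyperspectral Tissue
    Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Spectral-spatial classification of labeled hyperspectral cubes
    with a Sharpened Cosine Similarity (SCS) layer: ENVI and array-container
    I/O for cubes and label masks, factor-analysis band reduction, patch
    extraction around labeled pixels, stratified per-class splitting, an SCS
    classifier with absolute max-pooling trained by Adam alongside
    convolutional baselines, a Cohen's kappa / overall- and average-accuracy
    / F1 evaluation suite, a synthetic tissue-scene generator, and an
    end-to-end pipeline with classification-map rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
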