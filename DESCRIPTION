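Package: tcformer
Title: Temporal Convolutional Transformer for EEG Motor-Imagery Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements TCFormer, a compact temporal convolutional Transformer for
    decoding motor imagery from multichannel EEG. The architecture combines a
    multi-kernel convolutional front-end with grouped squeeze-and-excitation
    attention, a Transformer encoder using grouped-query attention with rotary
    positional embeddings, and a grouped dilated-causal temporal convolutional
    network classification head. The package provides the full training stack
    (Adam with linear warm-up and cosine decay, segmentation-and-reconstruction
    data augmentation, within-subject and leave-one-subject-out evaluation
    protocols, macro accuracy and Cohen's kappa), a neutral binary trial-store
    container with an optional GDF benchmark adapter, and a synthetic
    motor-imagery EEG generator with a band-power oracle classifier so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
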