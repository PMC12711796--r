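Package: lbsdet
Title: Lightweight Adaptive-Weighted Strawberry Ripeness Detector Components
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.com")
Description: Building blocks and desk-scale tooling for a lightweight
    strawberry-ripeness object detector derived from an anchor-free
    single-stage architecture: adaptive-weighted attention downsampling,
    gated star bottleneck blocks, learnable-weight bidirectional feature
    pyramid fusion, exact trainable-parameter and FLOP accounting for the
    assembled network and its ablation variants, five-grade fruit-ripeness
    scoring from HSV red-pixel proportion with graph-cut segmentation,
    detection metrics (precision, recall, F1, 11-point AP50, mAP50,
    mAP50-95, normalized confusion matrices), and a synthetic-scene
    generator with exact ground truth for end-to-end testing without the
    original photographic dataset.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    png,
    igraph,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
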