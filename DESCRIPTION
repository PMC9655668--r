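Package: encanet
Title: Attention-Based Blood Cell Detection with Exact Model-Complexity Audits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and trains ENCANet, a single-level anchor-based detector for
    blood-smear microscopy (platelets, red and white blood cells): an
    EfficientNet-B0..B3 feature extractor, a pluggable attention encoder
    (SE, ECA, CAM, ECAM, spatial attention, CBAM, ECBAM) and a dual-head
    depthwise-separable decoder. Provides pure-R reference implementations of
    every attention operator, an exact trainable-parameter audit of every model
    variant, COCO-format dataset input/output with the 7:2:1 split protocol, a
    synthetic blood-smear scene generator with COCO annotations, SGD training
    with focal and GIoU losses and uniform anchor matching, MS-COCO evaluation
    metrics, and attention-map visualization. The forward/backward compute
    engine is written in C++ (Rcpp/RcppArmadillo).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp (>= 1.0.0),
    jsonlite,
    png,
    EBImage,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
SystemRequirements: C++17
Config/testthat/edition: 3
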