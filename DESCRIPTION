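Package: painface
Title: Facial Pain Expression Recognition from Video Frame Streams
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects pain expressions in face videos by combining a
    Procrustes/PCA statistical shape model, per-landmark patch templates with
    constrained local-model fitting, point-operation image enhancement
    (logarithm and power-law transforms), six-parameter head-pose features and
    a 9-bin local binary pattern histogram, and a soft-threshold Euclidean
    distance classifier into neutral, pain and not-pain frame labels, with a
    multilayer backpropagation neural network as a comparison classifier.
    Includes a parametric synthetic face-video generator with ground-truth
    landmarks so the whole pipeline is testable without external data, plus
    hit-rate / false-acceptance-rate and ROC evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
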