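Package: stumpRBR
Title: Stump Detection and Root-and-Butt-Rot Severity Classification from
    RGB Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting harvested tree stumps in RGB images of
    post-harvest forest sites and grading the severity of root-and-butt-rot
    (RBR) visible on the cut surface. Provides a synthetic labeled-scene
    generator for benchmarking, a two-stage sliding-window CNN stump
    detector, bag-of-visual-words and CNN feature extractors, three
    interchangeable rot classifiers (BoF+SVM, CNN-features+SVM, fine-tuned
    CNN), the segmentation-quality (sq) overlap statistic, and an
    evaluation layer producing sq-thresholded detection metrics and
    per-class confusion-matrix accuracies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    e1071,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
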