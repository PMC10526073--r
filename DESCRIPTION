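Package: BeakFusion
Title: Shallow and Deep Feature Fusion for Cephalopod Beak Image Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies cephalopod species from images of their beaks by fusing
    local shallow descriptors with global deep features. Implements circular
    uniform local binary patterns (LBP) and histogram-of-oriented-gradients
    (HOG) descriptors, a residual convolutional backbone trained natively in R
    whose pooled penultimate activations serve as deep features, vector-stacking
    feature fusion, one-vs-rest RBF support vector machine classification, and
    confusion-matrix evaluation. Ships a parametric generator of beak-like
    labeled images (class-specific contour geometry and pigmentation texture at
    controllable difficulty) so the full pipeline is testable end to end, plus a
    staged, manifest-tracked command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    EBImage,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
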