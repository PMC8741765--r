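Package: tonguenet
Title: Deep Radial Basis Function Networks for Tongue-Feature Diabetes
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a deep radial basis function neural network
    classifier for Traditional Chinese Medicine tongue-feature diagnosis of
    diabetes mellitus. Hidden units use Gaussian radial activations whose
    centers are initialized by k-means clustering; layers are pretrained as
    greedy stacked autoencoders and fine-tuned by mini-batch gradient
    descent. The package also provides a deterministic encoding of
    categorical tongue features, a synthetic cohort generator with a
    class-conditional logistic effect model, confusion-matrix diagnostics
    with ROC curves, the 5x2 cross-validation paired t-test for comparing
    classifiers, and a reproducible experiment pipeline with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
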