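Package: mstnn
Title: Multiple Spatio-Temporal Scales Neural Networks for Dynamic
    Visual Pattern Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Recurrent-convolutional networks whose units are leaky
    integrators with a hierarchy of time constants, for classifying
    short grayscale image sequences such as binarized action
    silhouettes. Implements the single-step and full-sequence forward
    dynamics, exact backpropagation through time with a delay-response
    Kullback-Leibler loss, stochastic gradient training with an
    adaptive learning rate, a synthetic silhouette-video generator,
    moving-stripe occlusion and action concatenation transforms,
    leave-one-subject-out evaluation with majority voting over the
    delay window, and tools for analysing internal dynamics (activation
    traces, snapshot PCA, nested-cluster scores, top-layer time-constant
    ablation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    EBImage,
    nnet,
    cluster
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
NeedsCompilation: yes
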