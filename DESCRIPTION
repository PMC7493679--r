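Package: gaitlab
Title: Synthetic Point-Light Walkers and Sequence-vs-Static Gait Classification Benchmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Generates cohorts of synthetic point-light walkers (20-joint 3D
    skeletal trajectories on a virtual treadmill) with configurable
    gender-conditional dynamic (lateral sway) and structural cues, and
    benchmarks biomimetic sequence classifiers (a long short-term memory
    network trained by backpropagation through time) against non-biomimetic
    static classifiers (support vector machines with linear, radial-basis and
    sigmoid kernels; a small random decision forest) for binary gender
    classification from gait. Includes the shared preprocessing transforms
    (height normalization, coronal projection, moving-average smoothing,
    temporal differentiation, duration windowing, train-frozen scaling), two
    static featurizations (four first-order statistics per dimension; twelve
    clinical spatiotemporal gait metrics with heel-strike and toe-off event
    detection), subject-wise stratified cross-validation, exposure-duration
    sweeps, and the one-sample t and variance-ratio F statistics used to
    summarize them.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    rlang,
    jsonlite,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
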