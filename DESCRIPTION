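Package: surgstress
Title: Surgeon Stress and Ergonomics Analysis from Multimodal Sensor Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying operator stress and ergonomic load during
    robot-assisted surgical training from multimodal sensor recordings. The
    package computes the Baevsky Stress Index from RR-interval series,
    reconstructs hand trajectories from fiducial-marker pose observations by
    rebasing them into a fixed reference-marker frame, reduces posture
    landmark series to vertical-displacement metrics, assembles a per-trial
    metric table with significance-tiered Pearson correlations against the
    stress index, and classifies skill-related workload responses from
    approximate-entropy features using grid-searched decision-tree,
    k-nearest-neighbour, support-vector and logistic-regression classifiers
    under leave-one-out and k-fold cross-validation. A seed-deterministic
    synthetic cohort generator with planted stress and skill structure allows
    every pipeline stage to be exercised end to end without access to
    restricted clinical recordings.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    e1071,
    glmnet,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    withr
Config/testthat/edition: 3
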