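Package: ethotox
Title: Automated Behavioural Toxicology for Walking Insects in Circular Arenas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of open-field assays of a single walking
    insect in a circular (Petri-dish) arena, as used in sublethal pesticide
    screening. Provides fully automatic head/back labelling of video frames by
    threshold segmentation and progressive morphological erosion, export of
    detection-format training datasets, keypoint trajectory conditioning,
    behavioural feature extraction (kinematics, stop bouts, zone preference,
    wall-following/thigmotaxis, turning), probit concentration-mortality
    estimation of lethal concentrations with confidence limits, nonparametric
    group statistics (Shapiro-Wilk gate, Kruskal-Wallis, Dunn post hoc with
    Holm correction), nested cross-validated classification (SVM, random
    forest, K-nearest neighbours) with exact Shapley feature attributions, and
    a synthetic arena generator with exact ground truth for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    zoo,
    e1071,
    ranger,
    class,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
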