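Package: gazevalence
Title: Recognizing Image Valence from Observers' Eye Movements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for recognizing the affective valence class (unpleasant,
    neutral, pleasant) of an image from the eye movements of people who viewed
    it. Implements ten scanpath feature representations (fixation-density
    saliency maps, top salient locations, spatial fixation histograms, and
    histograms of fixation duration and of saccade duration, length, slope,
    velocity and orientation), one-versus-rest support vector machine
    classification under a repeated stratified cross-validation protocol
    scored by multiclass Bookmaker informedness, and a battery of feature
    reduction and wrapper selection schemes (PCA, SVD, sequential
    forward/backward selection, binary genetic algorithm, mutated binary
    particle swarm optimization) with a feature-contribution analysis. A
    synthetic gaze-data generator with class-conditional effects allows the
    whole pipeline to be exercised without access to proprietary
    eye-tracking corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
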