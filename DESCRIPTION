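Package: acidtrace
Title: Tracking Ratiometric pH Microsensors and Estimating Endosomal
    Acidification Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An automated analysis pipeline for time-lapse two-channel
    fluorescence recordings of micrometer-sized ratiometric pH probes.
    Detects probes by band-pass filtering and local-maximum selection,
    converts two-channel intensities to pH through an intensity-weighted
    log-ratio estimator and a monotone LOESS calibration curve,
    reconstructs trajectories with a linear-assignment-problem tracker
    with gap closing, classifies each trajectory as an outer, caging or
    inner event via quantile embedding, PCA and k-means++, and estimates
    acidification times for caging events by isotonic regression.
    Includes synthetic-data generators (Vicsek self-propelled particle
    trajectories, rendered two-channel image stacks, archetype pH tracks
    and calibration fixtures) used to validate every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
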