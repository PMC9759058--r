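Package: AlveoTrack
Title: Segmentation and Respiratory-Cycle Analysis of Two-Channel Lung
    Intravital Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Offline analysis of two-channel intravital microscopy videos of
    the ventilated lung: non-local-means denoising and mask formation per
    channel, contour extraction of dark alveolar airspaces and bright
    neutrophils with area restrictions, a temporal-consistency filter that
    keeps a detection only if a matching feature exists in a neighboring
    frame, per-frame feature statistics, respiratory-cycle segmentation of
    the alveolar-area time series, and two-experiment comparison analytics.
    Includes a parametric synthetic scene generator with per-frame ground
    truth so the whole pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    EBImage,
    tiff,
    png,
    jsonlite,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
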