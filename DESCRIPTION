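Package: rtqibc
Title: Retrospective Time-Lapse Synchronized Quantitative Image-Based Cytometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for retrospective time-lapse synchronized quantitative
    image-based cytometry (RT-QIBC): flat-field and bleedthrough correction of
    fluorescence microscopy images, nuclear segmentation with curvature-based
    splitting of touching nuclei, nearest-neighbour tracking with
    intensity-conservation repair and mitosis detection, cell-cycle event
    annotation on reporter traces (CRL4-Cdt2 degradation onset, APC/C-Cdh1
    inactivation, PCNA-foci S-phase entry), registration and matching of
    end-point fixed-cell images to live-cell tracks, Hill dose-response fitting
    of single-cell EdU incorporation, percentile gating, bootstrap statistics,
    and Pearson colocalization with a pixel-shift randomization null. A seeded
    synthetic-microscopy generator provides ground-truthed movies, fixed-plate
    snapshots and dose-response tables for benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
LinkingTo:
    Rcpp
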