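Package: ebclock
Title: Developmental Clock Analysis of Embryoid Body Reporter Kinetics and
    Single-EB Expression Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying early mesendoderm differentiation in
    embryoid bodies (EBs) from live reporter imaging and single-EB qPCR
    panels. Fits the five-parameter impulse (double-logistic) model to
    per-EB Brachyury-GFP point-count time courses, detects onset and peak
    events by threshold crossing, and defines a per-EB developmental clock
    (developmental age, DevA) as time since reporter onset. Includes 3D
    point-cloud clutter filters (close-neighbor and bounding-box), minimal
    enclosing circle radius estimation, housekeeping-gene stability ranking
    (geNorm M value and a NormFinder-style inter/intra-group decomposition),
    -ddCt normalization against control-group medians, nearest-neighbor
    imputation, correlation-based hierarchical clustering, local linear
    kernel trend smoothing along the clock, perturbation-shift statistics,
    PCA of perturbation groups, and a classifier of Wnt3-dependency modes
    under canonical Wnt activation. A synthetic cohort generator produces
    reporter time series, spherical-shell point clouds and CT matrices with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
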