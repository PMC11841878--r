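Package: canopyhsm
Title: Habitat Suitability Modelling from Canopy Height Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Presence-background habitat suitability modelling of old-forest
    nesting habitat from canopy height surfaces. Extracts individual trees
    (tree approximate objects) from a canopy surface by local-maxima
    detection, computes circular moving-window tree statistics on an
    analysis grid, draws spatially balanced (Halton / balanced acceptance)
    samples of used and available locations, fits an L1-regularised
    maximum-entropy model with linear, quadratic, product and hinge
    features, classifies habitat from the continuous predicted-to-expected
    (Boyce) ratio curve via exhaustive piecewise-linear breakpoint search,
    delineates habitat patches with concave hulls and morphological
    perimeter smoothing, and evaluates predictions (AUC, sensitivity,
    positive predictive value, Cohen's kappa, marginal response curves).
    A synthetic forest generator lets the full pipeline run end-to-end
    without proprietary LiDAR or survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
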