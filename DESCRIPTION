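Package: ensdm
Title: Ensemble Species Distribution Modelling with AIC Multimodel
    Averaging and Protected-Area Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for effort-corrected species distribution modelling on a
    regular planar grid: seasonal gridding of sightings with a minimum-effort
    filter, Spearman-rank collinearity screening resolved by univariate AIC,
    all-subsets GLM and fixed-df spline GAM fitting for presence-absence and
    negative-binomial count responses with a log-effort offset, Akaike-weight
    multimodel averaging over the 95% confidence set, concordance-index
    (C-index) temporal cross-validation, Moran's I residual diagnostics and
    permutation correlograms, C-index-weighted ensemble consensus surfaces,
    classification of habitat into recurrent, occasional and unfavourable
    areas, derived abundance surfaces, and overlap assessment against a marine
    protected area. A synthetic-data generator emulating a coastal survey
    system (smoothed environmental fields, feature-distance layers, uneven
    survey effort, a two-layer virtual species) makes every stage testable
    offline with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    splines,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ape,
    survival,
    pROC,
    mgcv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
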