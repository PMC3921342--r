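Package: bymcar
Title: Bayesian Spatial Disease Mapping with BYM Models, DIC Selection and
    Map Decomposition
Version: 0.1.0
Authors@R: person("Areal", "Health Analytics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Small-area ecological analysis of aggregated health outcomes:
    standardized morbidity ratios and expected counts, ethnic diversity and
    deprivation indices (entropy, Simpson, Maly neighbourhood diversity,
    index of concentration at the extremes), exploratory factor analysis by
    principal-axis factoring with direct-oblimin rotation, Besag-York-Mollie
    (intrinsic CAR + unstructured heterogeneity) spatial regression fitted by
    Markov chain Monte Carlo with deviance information criterion forward
    covariate selection, and Law-Haining decomposition of posterior relative
    risk into covariate, spatially structured and unstructured surfaces.
    Includes a synthetic areal-data generator with known ground truth,
    GeoBUGS adjacency file input/output and GeoJSON areal map support.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
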