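Package: hurdlemap
Title: Spatial-Temporal Hurdle Models and Exceedance-Probability Mapping
    for Under-Reported Event Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits a two-part (hurdle) Bayesian hierarchical model for
    police-reported event counts observed on small areas such as census
    tracts: a binomial reporting part and a Poisson count part estimated
    jointly, sharing tract-level unstructured heterogeneity, a first-order
    random-walk temporal effect, and a Matern Gaussian spatial field
    evaluated at tract centroids.  Includes a synthetic-data generator for
    Voronoi tract geographies with deprivation-style covariates and
    selection-biased counts, quintile covariate coding with a
    principal-component deprivation index, MCMC inference (elliptical
    slice sampling for latent fields, adaptive Metropolis for fixed
    effects and hyperparameters) with split-Rhat and effective-sample-size
    diagnostics, posterior relative-risk surfaces with exceedance
    probabilities and 80/20 hotspot classification, and GeoJSON/CSV export
    of map-ready layers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
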