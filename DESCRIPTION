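Package: stemmosaic
Title: Spatial Structure of Frequent-Fire Conifer Forests from Stem Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of mapped forest stands in frequent-fire conifer types:
    pair-correlation-function inference with Ripley isotropic edge correction
    and Monte Carlo null-model envelopes (complete spatial randomness,
    inhomogeneous Poisson, toroidal independence, random labeling), a
    Loosemore-Ford goodness-of-fit test, crown-width allometry with the
    Hopkins bioclimatic index, crown-overlap patch and morphological
    canopy-gap delineation with edge-buffer bookkeeping, patch typology by
    principal components and Ward clustering, composite fire-return-interval
    statistics, and a synthetic stem-map generator for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    igraph,
    jsonlite,
    generics,
    EBImage,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
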