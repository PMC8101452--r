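Package: nichecast
Title: Bootstrap Mahalanobis Climate-Niche Models and Ecosystem-Service
    Change Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Presence-only climate-niche modelling for ecosystem-service
    assessment. Builds a principal-component environmental space from a
    stack of bioclimatic variables (log-transformed rainfall, z-scored,
    PCA), fits bootstrap fundamental-niche ellipsoids by Mahalanobis
    distance with chi-square within-niche probabilities, projects
    potential-niche probability surfaces and areas under current and
    future climate scenarios (GCM x RCP x period ensembles with random
    GCM draws), and pools bootstrap percentage-point area changes by
    ecosystem service. Includes a synthetic-data module (virtual climate
    grids, future ensembles, virtual species with known niches, service
    catalogues) so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
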