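Package: metastab
Title: Linear Stability of Trophic Metacommunities with Allometric Dispersal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generates allometrically structured niche-model food webs placed
    on random geometric networks of habitat patches, samples spatially
    heterogeneous generalized-model parameters, and assembles metacommunity
    Jacobians that couple local food web dynamics through body-size-scaled
    dispersal. Provides eigenvalue-based classification of local and
    metacommunity stability, a permutation analysis that contrasts allometric
    dispersal hierarchies with random reassignments of the same dispersal
    rates, and ensemble drivers with binomial GLM / AIC attribution of
    stability to richness, connectance and dispersal parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
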