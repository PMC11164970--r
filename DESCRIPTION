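Package: envage
Title: Multiplexed Environmental Exposures and Multidimensional Aging Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how multiplexed environmental exposures (air
    pollution, residential green and blue space, road-traffic noise) relate to
    multidimensional aging metrics. Implements phenotypic age (PhenoAge) from
    the published Gompertz mortality-model equations, the Fried frailty
    phenotype score, weighted quantile sum (WQS) mixture regression with
    split-sample bootstrap weight estimation, self-organizing-map (SOM)
    discovery of exposure-pattern subpopulations with WSS/BSS cluster-count
    selection, covariate-adjusted association scans with Benjamini-Hochberg
    false-discovery-rate control, a latent-class model for socioeconomic
    status, and a seeded Gaussian-copula synthetic cohort generator that
    emulates the exposure correlation structure of a UK population cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
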