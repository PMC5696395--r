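Package: phylofa
Title: Phylogenetic Signal in Compositional Fatty-Acid Trait Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures phylogenetic signal in compositional fatty-acid (FA)
    profiles of arthropod species. Provides compositional preprocessing
    (rare-FA elimination, renormalization, adjusted logit transform, species
    means with standard errors), eigen-decomposition PCA with broken-stick
    axis retention, FA trophic-biomarker indices, Blomberg's K with and
    without measurement error, Pagel's lambda by maximum likelihood,
    permutation and Brownian-motion simulation null models, per-family
    multiple-testing correction, a dual-metric signal decision, and a seeded
    synthetic-data generator emulating replicate compositional FA
    measurements on a phylogeny. Tidyverse-native: tabular inputs and outputs
    are tibbles, fitted objects have tidy() and glance() methods and
    autoplot() figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
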