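Package: nectarphylo
Title: Phylogenetic Comparative Analysis of Nectar Sugar Traits and
    Pollinator Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative analysis of floral nectar carbohydrate
    traits on a phylogeny. Summarizes per-sample sucrose/glucose/fructose
    masses into species-level proportion and production profiles, assigns each
    plant species its primary pollinator group from flower-visitation
    frequencies, estimates global phylogenetic signal (Abouheif's Cmean,
    Moran's I, Blomberg's K, Pagel's lambda) and local Moran's I hotspots with
    randomization tests, performs simulation-based phylogenetic ANOVA and
    MANOVA with Games-Howell post hoc comparisons, and fits Brownian-motion
    and multi-regime Ornstein-Uhlenbeck models of trait evolution over
    stochastic character maps of pollinator regimes, compared by AICc.
    Includes seeded generators for synthetic trees, regime histories, traits,
    nectar samples, and visitation records so every stage is testable with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    stats,
    utils
Suggests:
    phytools,
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
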