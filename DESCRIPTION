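Package: bicellum
Title: Individual-Based Simulation of Division of Labour and the
    Evolution of Ageing in Bicellular Organisms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An individual-based evolutionary simulator for the simplest
    multicellular organism: an adult made of two totipotent cells that
    share one clonal genotype. Each cell splits its resource pool among
    foraging, damage repair and reproduction according to evolvable,
    cell-type-specific softmax reaction norms, signals for a share of the
    jointly foraged resources, accumulates stochastic damage, and carries
    16 bi-allelic viability loci whose expression is gated by damage
    level. The package provides the per-cycle physiology, mutation
    operators, a fast compiled population engine with three mortality
    rounds and optional regeneration, experiment presets, replicate
    runners, and summaries of division of labour, damage-specific allele
    frequencies and age-specific mortality, for studying the emergence of
    germ-line-soma separation, damage partitioning and senescence by
    mutation accumulation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
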