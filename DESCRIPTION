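Package: adaptrona
Title: Genotype-Environment Association, Risk of Nonadaptedness and
    Assisted Gene Flow Planning for Fragmented Plant Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A population-genomic pipeline for assessing local adaptation
    from population allele-frequency data. Detects environment-associated
    loci with a covariance-aware (whitened regression, Zellner g-prior)
    Bayes factor test over a drift null model, estimates per-population
    maladaptation as the current and future risk of nonadaptedness
    (c-RONA / f-RONA) via multi-locus ridge BLUP with REML variance
    components, ranks populations for conservation with the Shapley index
    on genetic-distance trees, and plans assisted gene flow by matching
    donor to recipient populations. Includes a synthetic-data generator
    (Balding-Nichols drift plus logistic environmental coupling) with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
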