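Package: lupinest
Title: Seed Dormancy, Soil Performance and pH Response Analytics for
    Early Establishment in Lupins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multi-experiment early-establishment
    trials in Lupinus species. Computes germination and physical-dormancy
    metrics (final germination percentage, mean germination time, Maguire
    velocity index, interpolated days to 50% germination, physical
    dormancy) from long-duration weekly censuses, with Kaplan-Meier
    curves and log-rank tests; derives ordinal establishment outcomes
    across contrasting soils with Wilson binomial intervals and
    fixed-effects logistic models fitted by iteratively reweighted least
    squares; analyses pH-by-time seedling growth with two-way ANOVA,
    seeded permutation max-|t| multiple comparisons, polynomial pH
    response and logit-allocation regression; and synthesises results
    through z-scored PCA, Ward.D2 clustering with bootstrap co-clustering
    support, a Spearman/Benjamini-Hochberg correlation screen, an
    Integrated Selection Index, and soil-matched accession
    recommendations. Includes seeded synthetic-data generators that
    emulate the statistical structure of the three experiments, soil
    physicochemical handling with charge-equivalent cation ratios, and a
    one-call reproducible pipeline with a JSON run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    car,
    cluster,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
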