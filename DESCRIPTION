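Package: oleadiv
Title: Integrated Morphometric, Biochemical and Microsatellite Diversity
    Analysis for Olive Germplasm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising diversity in olive (Olea europaea L.)
    germplasm collections from three kinds of evidence: codominant SSR
    (microsatellite) genotypes, quantitative morphometric traits, and the
    fatty-acid composition of the oils. Provides GenAlEx-style per-locus
    diversity indices (Na, Ne, Ho, He, uHe), Brookfield null-allele
    estimation, a Monte-Carlo exact test of Hardy-Weinberg equilibrium,
    multilocus-genotype (clone) identification with Pgen, Dice-Sorensen
    genetic distances with Ward dendrograms, Evanno delta-K post-processing
    of admixture log-likelihoods, a nonparametric group-comparison pipeline
    (Kruskal-Wallis with the Siegel-Castellan post-hoc), PCA with PAM
    clustering diagnosed by the gap statistic and silhouette widths, and
    Mantel permutation tests relating geographic, morphometric, biochemical
    and genetic distance matrices. A seeded synthetic-data generator
    emulates the structure of a four-site Campanian germplasm survey so
    every stage of the pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    cluster,
    mclust,
    ape,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
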