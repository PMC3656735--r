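Package: msatmerge
Title: Harmonization and Population-Structure Analysis of Multi-Study
    Microsatellite Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for merging heterogeneous diploid microsatellite genotype
    panels genotyped in different studies. Infers per-locus integer allele-size
    offsets between data sets from duplicate samples via identity-by-state
    allele sharing, classifies loci as exact, offset, or mismatch, applies
    missing-data quality filters, screens for cryptic relatives with a
    composite-likelihood relationship classifier, and constructs standardized
    unrelated subsets. Downstream population-structure analyses include
    allele-sharing distances, classical multidimensional scaling, Procrustes
    comparison to geography with a population-block permutation test,
    neighbor-joining trees with locus-bootstrap greedy consensus, expected
    heterozygosity corrected for close relatives, and waypoint-routed
    great-circle distances for serial-founder diversity gradients. A
    synthetic-data generator with a full truth record supports validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    geosphere,
    stats,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
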