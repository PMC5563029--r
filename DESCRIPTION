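Package: offtypeR
Title: Genotypic and Phenotypic Screening of Off-Type Grasses in Clonal
    Turfgrass Cultivars
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for fingerprinting clonally propagated turfgrass
    cultivars and screening off-type samples with genotyping-by-sequencing
    and morphology. Provides a ploidy-aware genotype model backed by
    multi-sample VCF, pooling of clonal replicates with dosage re-calling,
    identification of informative (differentiating) variants between
    cultivar pairs under read-depth windows, Venn partitioning of variant
    sets across ploidy groups, identity-by-state dosage distances with
    classical multidimensional scaling and a robust divergent-sample
    screen, flow-cytometry genome-size estimation against an internal
    standard, K-means clustering of morphological traits with the cubic
    clustering criterion, a seeded synthetic-data generator emulating the
    study design, and an end-to-end pipeline driver.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    withr
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
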