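Package: caprascape
Title: Landscape Genomics and Climate Projection for Goat SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for multi-breed livestock landscape genomics
    from SNP-array genotypes: PLINK text input/output and quality control
    (call rate, minor allele frequency, linkage-disequilibrium pruning,
    duplicate and relative removal, representative subsampling), population
    structure via identity-by-state distances, classical multidimensional
    scaling, Reynolds distances with bootstrap neighbor-joining trees,
    breed-level identity-by-descent haplotype-sharing summaries, per-genotype
    logistic likelihood-ratio genotype-environment association with principal
    component structure correction and Benjamini-Hochberg control, and
    projection of future allele and genotype frequencies under Hardy-Weinberg
    equilibrium from Koppen-Geiger climate-class groupings. A seeded
    Balding-Nichols simulator generates structured multi-breed genotypes with
    environmental clines and planted identity-by-descent segments so every
    stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
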