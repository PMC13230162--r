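Package: boarMicrobiome
Title: Breed, Farm and Age Structure in the Boar Gut Metagenome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for large shotgun-metagenomic surveys of
    commercial boar gut microbiota. Provides coverage-gated species presence
    calling on TPM abundance tables, alpha and beta diversity with principal
    coordinates analysis, a from-scratch distance-based multivariate variance
    partitioning (PERMANOVA) with sequential and marginal R2, bootstrap
    subsampling to assess robustness of diversity comparisons under
    imbalanced breed group sizes, UpSet-style shared-taxa set analysis
    across breeds and farms, and covariate-adjusted per-taxon log-linear
    enrichment models with a cross-comparison consistency classifier.
    Includes a synthetic cohort generator emulating a three-breed,
    three-farm boar station design so the whole chain is testable without
    the deposited sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    vegan,
    yaml,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
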