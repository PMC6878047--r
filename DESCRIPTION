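Package: wingqtl
Title: Multi-Layer Omics Analysis of Wing-Size Variation in Inbred Fly Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the genetic architecture of a quantitative
    organ-size trait measured across a panel of fully inbred lines, such as
    the Drosophila Genetic Reference Panel. The package covers RNA-seq count
    preprocessing (library and count filtering, log-CPM with mean-variance
    precision weights, principal-component batch removal), sex-adjusted
    trait-expression association of three types (whole-population, within-sex
    ANCOVA, and sex-dimorphism ANOVA) with Benjamini-Hochberg correction,
    cis/trans eQTL mapping with permutation minimum-p multiple-testing
    correction and empirical FDR, triangular mediator-gene selection
    (genotype - expression - phenotype), and an additive unit-sign eQTL score
    that predicts line-level size from genotype alone. A fully self-contained
    synthetic cohort generator with known ground truth supports power,
    calibration and recovery studies without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    vcfR,
    withr,
    jsonlite
Config/testthat/edition: 3
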