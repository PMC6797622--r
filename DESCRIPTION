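Package: hornherit
Title: Marker-Based Heritability and GWAS of Horn Size from Harvest Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-genetic analysis of horn size in harvested mountain
    sheep from annuli-based repeated measures and SNP-chip genotypes.
    Reconstructs yearly horn length, base circumference and frustum volume
    from per-annulus measurements with the standard plausibility filters,
    performs PLINK text genotype quality control, builds an allele-frequency
    weighted genomic relationship matrix, fits a five-component
    repeated-measures animal model (additive genetic, permanent environment,
    birth-year cohort, year of measurement, residual) by average-information
    REML to estimate narrow-sense heritability, and runs a covariance-aware
    single-SNP Wald association scan with genomic control. Includes a
    simulation module that generates half-sib pedigrees, gene-dropped
    genotypes and annuli-structured phenotypes with known variance
    components, so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
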