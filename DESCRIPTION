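Package: structgp
Title: Genomic Prediction in Structured Germplasm with RR-BLUP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ridge-regression best linear unbiased prediction (RR-BLUP) for
    genomic prediction in germplasm collections with strong population
    structure, such as the two diverged gene pools (Andean and Mesoamerican)
    of the common bean. Provides an exact restricted maximum likelihood
    (REML) mixed-model solver based on a spectral decomposition of the
    genomic kernel, VCF genotype import with minor-allele-frequency and
    missingness filtering and proportional per-chromosome marker
    subsampling, principal component analysis of genotypes,
    predictive-ability and top-ranking overlap metrics, cross-validation
    designs over training-population size and marker number, gene-pool
    combine/assign prediction designs, and training-set optimization
    scenarios that add breeding lines to landrace training sets. Includes a
    seeded two-gene-pool cohort simulator (Balding-Nichols allele-frequency
    divergence, additive traits at configurable heritability) so the whole
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    cluster,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
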