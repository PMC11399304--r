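Package: sexstratgen
Title: Sex-Stratified Genetic Architecture of Quantitative Traits
Version: 0.1.0
Authors@R:
    person("sexstratgen", "maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing the common-variant genetic architecture of
    quantitative (neuroanatomical) traits between males and females:
    genotype/phenotype simulation with known per-sex heritability and
    between-sex effect correlation, variant- and sample-level quality
    control, autosomal and X-chromosome genetic relationship matrices under
    alternative dosage-compensation codings (with GCTA-compatible binary
    I/O), average-information REML for univariate multi-GRM heritability and
    the bivariate between-sex genetic correlation with boundary-aware
    likelihood-ratio tests, sex-stratified linear genome-wide association,
    per-SNP and per-trait sex-difference z statistics with strict and relaxed
    multiple-testing tiers, variance-decomposition comparisons, and
    spin-permutation spatial enrichment of cortical maps against functional
    networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
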