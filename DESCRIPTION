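Package: peagain
Title: Genomic Selection and Genotype-by-Environment Analysis for Connected RIL Populations
Version: 0.1.0
Authors@R:
    person("Pea", "Breeding Analytics", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for genomic selection in multi-environment trials
    of connected recombinant inbred line (RIL) populations, as used in pea
    breeding. Provides marker quality control (missing-rate and minor allele
    frequency filters, mode and iterative random-forest imputation), VanRaden
    genomic kinship and Nei's standard genetic distance, balanced-design
    variance-component estimation with broad-sense heritability and genetic
    correlations, AMMI decomposition of genotype-by-environment interaction
    with the F_R axis test and nominal yields, three whole-genome regression
    models (ridge-regression BLUP, G-BLUP, Bayesian Lasso) with optional
    population-structure fixed effects, stratified cross-validation under
    intra/inter-environment and intra/inter-population scenarios, a genomic
    versus phenotypic selection efficiency calculus based on truncation
    selection intensities, and a structure-corrected association scan with
    genomic-control inflation correction and Benjamini-Yekutieli FDR. A
    synthetic-data generator emulating connected F6 RIL populations in
    randomized complete block trials makes the whole pipeline testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    S4Vectors,
    lme4
Config/testthat/edition: 3
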