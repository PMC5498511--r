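Package: panelsim
Title: Simulation of Marker-Panel Design for Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates genomic-selection experiments that compare trait-prediction
    accuracy across marker panels defined by linkage disequilibrium (LD) with the
    causal loci. Provides a haplotype-mosaic genotype simulator for inbred diversity
    panels with controllable minor-allele frequency, LD decay and population
    structure; additive quantitative-trait simulation at a specified heritability;
    construction of seven LD-defined marker panels (QTL-only, QTL plus highest-LD
    markers, genome-wide, highest-LD proxies, genome-wide minus QTL, relaxed-LD
    proxies, and proxies plus random markers); from-scratch whole-genome regression
    (ridge-regression BLUP with REML variance components, and Bayes-B / Bayes-C
    single-site Gibbs samplers); and a replicated train/validation experiment
    driver that reports validation-set prediction accuracies as tidy tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
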