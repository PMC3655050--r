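Package: f2impute
Title: Pedigree-Based Genotype Imputation Accuracy in F2 Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for linkage-based genotype
    imputation in three-generation F2 resource populations. Simulates founder
    breed haplotypes and gene-dropping through an F0/F1/F2 pedigree, selects
    low-density tagSNP panels by linkage-disequilibrium cover or even physical
    spacing, imputes untyped markers in the progeny with grandparental-origin
    hidden Markov models (Haldane map function, forward-backward decoding on
    litter-based family units), and computes imputation-accuracy statistics
    (allelic-dosage IA, per-SNP R-squared, haplotyping accuracy and
    uncertain-phase fractions) under alternative genotyping scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
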