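Package: karstdemog
Title: Demographic Inference for Two-Cluster Plant Populations from
    Reduced-Representation SNP Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for coalescent-based demographic inference in a
    two-cluster population system genotyped at short multilocus stacks
    (MIG-seq/RAD-style SNP data). Provides Stacks 'populations'-style SNP
    filtering, standard diversity and differentiation statistics
    (observed/expected heterozygosity, F_IS, rarefied allelic richness,
    nucleotide diversity, Weir-Cockerham F_ST, Nei distance, Mantel
    isolation-by-distance test), construction of the folded
    two-dimensional minor-allele site frequency spectrum with
    within-cluster bootstrap imputation of missing genotypes, a
    structured-coalescent simulator for four two-population divergence
    models (staged size changes, windowed migration), maximum
    composite-likelihood fitting with AIC model selection, and
    parametric-bootstrap confidence intervals. A synthetic-data
    generator emits study-shaped datasets with known truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    vcfR,
    geosphere,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
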