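Package: msylineage
Title: Y-Chromosome Haplotype Backbones, Hierarchical Haplogroup Calling,
    and Paternal Ancestry Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for male-specific Y-chromosome (MSY) lineage analysis in
    stallion-centred breeding populations. Builds and validates
    variant-annotated haplotype backbone trees (perfect phylogeny from binary
    SNP matrices, labelled-Newick import/export, sub-haplogroup condensation),
    calls haplotypes hierarchically from partial genotypes with inner-node
    "*HT" allocation and imputation, computes haplotype-frequency spectra and
    Nei haplotype diversity per breed group, derives and applies
    haplotype-to-ancestry predictors, and dates clades with a strict-clock
    rho/Poisson estimator. Ships a synthetic-genealogy generator (Crown-like
    star expansions, Poisson infinite-sites mutations, line-breeding frequency
    skew, partial genotyping) so every stage is testable with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
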