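Package: ssrclust
Title: SSR Genotype Analysis for Germplasm Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of co-dominant microsatellite (SSR)
    genotype tables from plant germplasm collections: reading, validation
    and cross-laboratory allele-size harmonization; duplicate (clone)
    detection under a mismatch-tolerance rule with probability-of-identity
    reporting; putative-triploid flagging; per-locus diversity statistics
    (allele counts, effective alleles, observed and expected heterozygosity,
    rarefied allelic richness, private and unique alleles); a Bayesian
    admixture model fitted by Markov chain Monte Carlo with correlated
    allele frequencies, replicate-run alignment, Evanno delta-K model
    selection, membership-threshold assignment and nested substructure
    analysis; AMOVA and pairwise Weir-Cockerham F_ST with permutation
    tests; simple-matching dissimilarity, principal coordinate analysis
    and neighbor-joining trees; likelihood-based two-parent (trio)
    parentage with simulation-calibrated confidence; and a synthetic-data
    generator that emulates structured, clonally redundant germplasm so
    every stage can be verified against a known truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    ape,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
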