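Package: popdiffscan
Title: Population Differentiation Scans and Selective Sweep Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome scans for exceptionally high and low population
    differentiation based on derived allele frequencies (DAF). Implements
    pairwise delta-DAF and coefficient-of-variation (cvDAF) statistics with
    empirical rank P-values and windowed peak-picking, per-site Weir-Cockerham
    FST, extended haplotype homozygosity statistics (EHH, iHS, XP-EHH),
    classification of hard versus soft selective sweeps from the
    frequency-weighted Levenshtein homogeneity of derived-allele haplotypes,
    a forward-time Wright-Fisher simulator of a three-population
    out-of-Africa demography with recombination, migration and controlled
    selective sweeps, a power/sensitivity benchmark against
    neutral-simulation thresholds, and gene-set enrichment and concordance
    statistics for validating candidate sites.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
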