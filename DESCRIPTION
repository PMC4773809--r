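Package: ptcpopgen
Title: Population Genetics of Premature Termination Codons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end, reproducible pipeline for population-level
    analysis of premature termination codons (PTCs, stop-gain variants).
    Classifies single-nucleotide stop gains against transcript open reading
    frames, polarizes alleles with primate outgroups to obtain derived
    allele frequencies, computes truncation geometry and nonsense-mediated
    decay (50-nt rule) susceptibility, estimates multi-population
    differentiation (Weir-Cockerham theta, Hedrick's G'ST, Jost's D) with
    bootstrap confidence intervals, tests Hardy-Weinberg equilibrium with
    an exact test, detects differentiation outliers by studentized-residual
    regression and percentile rules, summarizes population structure by PCA
    and hierarchical clustering, and performs virtual genotyping against
    archaic (Neanderthal/Denisovan) allele tables. Includes a
    Balding-Nichols synthetic-data generator so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
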