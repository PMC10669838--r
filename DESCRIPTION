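Package: sweepscan
Title: Selection-Signature Scanning with FST, XP-EHH and a Windowed
    Composite Likelihood Ratio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects selective sweeps that differentiate resequenced
    populations by combining three per-comparison tracks: per-SNP
    Weir-Cockerham FST with Fisher exact allele tests under Bonferroni
    correction, cross-population extended haplotype homozygosity (XP-EHH)
    with genome-wide normalization, and a windowed cross-population
    composite likelihood ratio (XP-CLR style) scan with linkage
    down-weighting and a top-1 percent rule. Significant SNPs are grown
    into selected regions by a seed-and-extend caller, regions are
    annotated against a GFF3 gene set, and genes supported by at least two
    of the three methods become final candidates. Includes diversity
    statistics (observed heterozygosity, gene diversity, IBS distance),
    SNP quality filters (MAF, exact Hardy-Weinberg test, missingness), and
    a seeded Balding-Nichols simulator that emits phased multi-population
    VCF panels with injected sweeps so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    vcfR,
    ape,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
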