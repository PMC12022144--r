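Package: admixscan
Title: Selection Scans and Local Ancestry Deviation Analysis for Admixed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Haplotype-based genome scans for recent positive selection and
    post-admixture selection. Implements the singleton density score (SDS)
    with derived-allele-frequency-binned standardization, cross-population
    extended haplotype homozygosity (XP-EHH) with genome-wide
    standardization, an empirical-quantile peak caller with a
    supporting-variant window rule, and a local ancestry deviation (LAD)
    scan with overlap reporting against selection peaks. Includes forward
    Wright-Fisher simulation of neutral and selective-sweep haplotype
    panels (singletons retained, alleles polarized by the founding state)
    and Markov admixture-tract simulation, plus readers and writers for
    phased VCF, PLINK-style genetic maps, RFmix-style local-ancestry
    tables, and BED intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
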