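Package: pansweep
Title: Haplotype-Based Selection Scans and Pangenome Set Accounting for
    Structurally Complex Livestock Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of multi-assembly pangenome variant sets
    and phased population cohorts: from-scratch extended haplotype
    homozygosity statistics (iHS and nSL) with derived-allele-frequency
    bin standardization, a windowed hysteresis peak caller for selective
    sweep regions, gene-peak intersection, support-vector annotation and
    structural-variant set (upset) accounting of multi-assembly VCFs,
    nonreference insertion-length accounting, kinship-based cohort
    pruning with coverage prioritization, karyotype fusion-point
    detection from PAF alignments with coordinate lifting, and
    impact-class enrichment of variants inside sweep regions. Includes
    seeded generators for every input (founder-mosaic haplotype panels
    with implanted sweeps, toy pangenomes with known presence patterns,
    kinship cohorts, fused-chromosome alignments) so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
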