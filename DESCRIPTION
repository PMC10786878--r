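Package: baitnet
Title: Bait-Centric IP-MS Interactor Calling, PPI Networks, and GWAS
    Locus Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline from immunoprecipitation mass-spectrometry (IP-MS)
    protein quantification tables to cell-type-specific protein-protein
    interaction (PPI) networks and their integration with genome-wide
    association study (GWAS) results. Implements median normalization,
    contaminant and evidence filtering, downshifted-normal imputation of
    missing intensities, per-replicate log2 fold changes, an empirical-Bayes
    moderated one-sample t-test with Benjamini-Hochberg false discovery rate
    control, quality-control gates, network assembly with cell-type
    partitions, one-tailed hypergeometric gene-set enrichment with global and
    conditional backgrounds, a SNP-wise mean gene-based association test with
    an LD-aware quadratic-form null, a competitive gene-set test for genetic
    risk enrichment, LD clumping of GWAS index variants, and PPI-guided
    prioritization of candidate genes in risk loci. A synthetic-data module
    generates every input format with the statistical structure the analysis
    assumes, so the full pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    fgsea,
    vcfR,
    ggplot2
Config/testthat/edition: 3
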