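Package: crossPleio
Title: Cross-Trait Pleiotropy, Concordance and Conditional FDR for GWAS
    Summary Statistics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying shared genetic architecture between two
    traits from genome-wide association study (GWAS) summary statistics
    alone. Implements allele harmonization across studies, greedy linkage-
    disequilibrium (LD) clumping conditioned on a secondary trait, SNP
    effect concordance analysis (grid-based pleiotropy and sign-concordance
    tests with permutation-derived empirical p-values), conditional false
    discovery rate (cFDR) re-ranking across nested conditioning subsets,
    and stratified true-discovery-rate curves for conditional QQ plots.
    Includes a seeded simulator of paired summary statistics over an
    LD-block genome with known shared-causal structure, so every stage is
    testable without access-restricted consortium data.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: GenomeWideAssociation, SNP, StatisticalMethod, MultipleComparison
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
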