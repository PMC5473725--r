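Package: smrheidi
Title: Summary-Data Mendelian Randomization with HEIDI Filtering for
    QTL-GWAS Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies genetic variants pleiotropically associated with a
    complex trait and a molecular phenotype (DNA methylation or gene
    expression) from summary statistics alone.  Implements the
    summary-data-based Mendelian randomization (SMR) test, which uses the
    top cis-QTL SNP as an instrumental variable to compare QTL and GWAS
    effect estimates, and the HEIDI (heterogeneity in dependent
    instruments) test, which distinguishes a single shared causal variant
    (pleiotropy) from distinct causal variants in linkage disequilibrium.
    Includes allele harmonization of summary tables, an LD reference
    backed by genotype dosages, multiple-testing control, replication and
    cross-tissue concordance summaries, eQTL overlap at the gene level,
    novel-locus flagging, multi-trait clustering of SMR t-statistics, and
    a generative simulator of genotypes, molecular traits, phenotypes and
    two-study summary statistics under pleiotropy, linkage and null
    scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite
Config/testthat/edition: 3
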