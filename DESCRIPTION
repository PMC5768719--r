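Package: gsmrkit
Title: Multi-Instrument Mendelian Randomization from GWAS Summary Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Generalized summary-data-based Mendelian randomization (GSMR):
    estimates the causal effect of an exposure on an outcome by combining
    per-SNP instrumental-variable ratio estimates with generalized least
    squares, accounting for sampling variance in both SNP-exposure and
    SNP-outcome effects and for linkage disequilibrium among instruments.
    Includes HEIDI-outlier filtering of pleiotropic instruments,
    multi-trait-based conditional GWAS adjustment (mtCOJO) from summary
    data, LD computation and P-value-ranked clumping from a reference
    genotype panel (PLINK bed/bim/fam or plain text), readers and writers
    for GCTA-COJO '.ma' summary statistics, IVW and Egger-regression
    comparators, and a seeded simulator of two-sample GWAS summary data
    for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite, yaml, optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
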