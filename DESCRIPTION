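Package: hybridforge
Title: Hybrid Genetics Analysis for NC-II Testcross Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for North Carolina II factorial testcross
    populations in hybrid crop breeding. Enumerates maternal-by-tester cross
    designs, filters parental SNP genotypes and derives F1 hybrid genotypes,
    processes multi-environment phenotypes (mixed-model BLUPs, z-score
    normalisation, mid-parent heterosis), fits gBLUP genomic prediction models
    with tester-structured cross-validation, runs mixed linear model
    genome-wide association scans (plain and conditional on a tag-SNP
    genotype), calls and merges QTLs with a linkage-disequilibrium-aware
    clumping algorithm, classifies QTLs into additive, dominant and epistatic
    heterotic classes, quantifies GWAS false discovery rate and detection
    power under predicted phenotypes with spike-in QTN simulations, and
    supports molecular design breeding through multi-locus haplotype group
    comparison and selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
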