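Package: ascnpipe
Title: Allele-Specific Copy Number Analysis of SNP-Array Tumor Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for allele-specific copy number (ASCN) analysis of tumor
    genomes from SNP-array-like data: change-point segmentation of log2
    copy-number ratios (logR) and mirrored B-allele frequencies (mBAF),
    lattice-based estimation of aberrant-cell fraction and in-silico tumor
    ploidy, per-segment allele-specific copy numbers, calling of gain/loss
    relative to tumor ploidy, loss of heterozygosity (LOH) and copy-number
    neutral allelic imbalance (CNN-AI), fraction-of-genome-altered summaries,
    detection of subclonal copy-number loss, focal/broad amplicon and
    monoallelic-amplification classification, permutation-based recurrent
    region discovery, and DNA flow-cytometry ploidy summarization. Includes a
    synthetic tumor-genome generator with known purity, ploidy and clonal
    structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
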