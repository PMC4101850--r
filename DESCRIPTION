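Package: csscan
Title: Composite Selection Signals for Two-Group Genome Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Localizes trait-specific signatures of selection in multi-breed
    diploid populations by contrasting a putatively selected sample group
    against a reference group.  Per-SNP constituent statistics (Wright's
    fixation index, the difference in derived or selected-allele frequency,
    and the cross-population extended haplotype homozygosity log-ratio) are
    combined through fractional ranks and an inverse-normal transform into a
    single composite selection signal, smoothed over 1 Mb sliding windows,
    and summarized as significant clusters and candidate regions with
    per-test concordance counts.  Empirical composite p-values are
    recalibrated and given tail-area false discovery rates.  A deterministic
    two-population hard-sweep simulator with a truth table supports
    calibration and power checks without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
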