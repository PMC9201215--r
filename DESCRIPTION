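Package: epipattern
Title: Effect-Pattern Epistasis Scans for Case-Control SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exhaustive single-, two- and three-SNP effect-pattern association
    scans for case-control genotype panels. Each SNP is decomposed into
    additive, dominant-deviation and recessive binary contrasts; multi-SNP
    exposure patterns are tested against disease status with
    covariate-stratified Cochran-Mantel-Haenszel tests, Mantel-Haenszel odds
    ratios with Robins-Breslow-Greenland confidence intervals, and
    Benjamini-Hochberg false-discovery-rate control. Also provides two-locus
    haplotype frequency estimation by expectation-maximization with
    carrier-model haplotype association tests, cross-disease comparison of
    significant interactions, genotype and sample table input/output (VCF and
    TSV), and a case-control cohort simulator with Hardy-Weinberg genotypes,
    linkage-disequilibrium pairs, confounders and planted pattern effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
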