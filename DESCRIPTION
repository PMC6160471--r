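Package: lipidmr
Title: Two-Sample Mendelian Randomization of Blood Lipids on Binary Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization with GWAS summary
    statistics, oriented towards lipid exposures and case-control outcomes.
    Covers harmonization of exposure and outcome association tables to a
    common effect allele, genome-wide and pleiotropy-restricted instrument
    selection, greedy linkage-disequilibrium pruning of cis drug-target
    variants, inverse-variance-weighted, MR-Egger and weighted-median causal
    estimators (including generalized least-squares versions for correlated
    instruments), heterogeneity and pleiotropy diagnostics (modified
    second-order-weight Q statistic, Egger intercept test, MR-PRESSO global
    and outlier tests), binary-outcome power calculations, and a synthetic
    summary-statistic generator with known causal truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    MASS
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
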