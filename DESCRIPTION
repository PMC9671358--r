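Package: mrkit
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A complete toolkit for two-sample Mendelian randomization (MR)
    from GWAS summary statistics: instrument selection (genome-wide
    significance screening, MAF filtering, greedy LD clumping, F-statistics),
    harmonization of exposure and outcome effect estimates to a common effect
    allele (strand flips, palindromic SNPs resolved by allele frequency),
    causal estimation by fixed- and multiplicative-random-effects
    inverse-variance weighting, weighted median and MR-Egger regression,
    sensitivity analysis (Cochran's Q heterogeneity, MR-PRESSO global and
    per-SNP outlier tests, leave-one-out, funnel-plot data), confounder-based
    instrument filtering, multivariable MR, and analytical power for binary
    outcomes.  Includes a seeded generator of synthetic two-sample GWAS
    summary data with known causal effect and configurable pleiotropy for
    method validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
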