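Package: mrpleio
Title: Two-Sample Mendelian Randomization with a Pleiotropy-Appraisal Battery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for two-sample Mendelian randomization from GWAS summary
    statistics: reading and validating summary tables, allele harmonization
    (including strand flips and palindromic-SNP resolution by allele
    frequency), instrument selection with greedy LD pruning, instrument
    strength and Cochran's Q diagnostics with radial outlier detection, a
    battery of causal estimators (inverse-variance weighted, MR-Egger with
    SIMEX regression-dilution correction, weighted median, weighted mode,
    and multivariable IVW for confounder adjustment), bidirectional
    appraisal with instrument-overlap exclusion, Benjamini-Hochberg FDR
    reporting, and a seeded generator of synthetic GWAS summary statistics
    under vertical, horizontal, and confounding pleiotropy models for
    calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
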