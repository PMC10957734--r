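Package: mrlink
Title: Two-Sample Mendelian Randomization with Sensitivity Analyses and
    Mediation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) from GWAS
    summary statistics: harmonization of exposure and outcome associations
    to a shared effect allele, selection of independent genome-wide
    significant instruments by greedy linkage-disequilibrium clumping,
    instrument-strength F statistics, inverse-variance-weighted, weighted
    median and MR-Egger causal estimators with Cochran's Q heterogeneity,
    Egger-intercept and MR-PRESSO pleiotropy tests, leave-one-out
    diagnostics, multivariable MR for direct effects, and two-step MR
    mediation with delta-method inference. A synthetic summary-statistics
    generator with known ground truth supports calibration and end-to-end
    validation without external data.
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
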