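Package: mrmediate
Title: Two-Step Mendelian Randomization Mediation Analysis from GWAS
    Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) mediation
    analysis using GWAS summary statistics. Implements instrument selection
    with distance clumping, allele harmonization, instrument-strength
    diagnostics, inverse-variance-weighted (IVW), MR-Egger, weighted-median,
    radial MR and MR-PRESSO estimators, multivariable MR for direct effects,
    a three-step mediator screen, and two-step MR mediation with
    delta-method standard errors for indirect effects and mediated
    proportions. Includes a generator of multi-trait GWAS summary statistics
    under a known exposure-mediator-outcome causal model so the whole
    pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
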