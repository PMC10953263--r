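Package: mrmediate
Title: Drug-Target Mendelian Randomization with Two-Step Mediation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for drug-target Mendelian randomization (MR) of GWAS
    summary statistics: harmonization of exposure and outcome associations,
    cis-instrument selection with eQTL filtering and LD clumping, Bayesian
    colocalization via Wakefield approximate Bayes factors, five two-sample
    MR estimators (inverse-variance weighted, MR-Egger, weighted median,
    simple and weighted mode) with Cochran's Q and Egger-intercept
    sensitivity statistics, a Bonferroni-screened metabolite mediator scan,
    and two-step MR mediation with delta-method confidence intervals for the
    proportion mediated. Includes a summary-statistic simulator with known
    causal structure for calibration and validation studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
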