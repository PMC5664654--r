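Package: longGxE
Title: Set-Based Gene-Environment Interaction Tests for Longitudinal Cohorts
Version: 0.1.0
Authors@R:
    person("HRS", "Methods Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Generalized estimating equation (GEE) machinery for testing
    whether sets of common genetic variants interact with dichotomous
    social/psychosocial exposures on a repeatedly measured quantitative
    outcome such as body mass index. Provides exposure battery scoring and
    dichotomization, gene/region construction around GWAS index SNPs with
    imputation-quality and allele-frequency filters, a Gaussian GEE engine
    with cluster-robust (sandwich) covariance, set-based score ("dispersion")
    tests of interaction and marginal genetic effects with spline adjustment
    for nonlinear exposure main effects and weighted-PCA adjustment for
    genotype main effects, mixture-of-chi-square p-values (moment matching
    and characteristic-function inversion), fixed-effect and Fisher
    meta-analysis across ancestry strata, Benjamini-Hochberg FDR, single-SNP
    follow-up scans, and a synthetic-cohort generator emulating an unbalanced
    two-exam panel study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
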