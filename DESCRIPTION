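Package: twingrowth
Title: Longitudinal Twin Modelling of Leukocyte Telomere Length
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for longitudinal analysis of leukocyte telomere length
    (LTL) measured as qPCR T/S-ratios in twin cohorts. Provides a synthetic
    twin-cohort generator with monotone attrition, plate batch effects and
    genetic risk alleles; plate batch adjustment and outlier exclusion for
    T/S-ratios; an un-weighted 7-SNP genetic risk score; cross-sectional
    linear regression with cluster-robust (sandwich) standard errors
    clustered on twin pair; piecewise latent growth curve mixed models with
    a knot in the age trajectory, between- and within-pair random effects,
    maximum-likelihood fitting and likelihood-ratio model comparison; and
    within-individual change metrics including the telomere elongation
    fraction and a tricube loess trend smoother.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    vcfR
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    sandwich,
    jsonlite,
    optparse
Config/testthat/edition: 3
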