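Package: metabomr
Title: Mendelian Randomization and Observational Survival Analysis of
    Circulating Metabolic Measures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline linking circulating metabolic measures to incident
    fatty liver disease, combining two-sample Mendelian randomization with
    prospective cohort analysis. Covers GWAS summary-statistic input and
    harmonization, instrument selection with LD clumping and proxy
    substitution, inverse-variance-weighted and robust causal estimators
    (MR-Egger, weighted median, contamination mixture, MR-PRESSO),
    Steiger directionality filtering, reverse MR, multivariable MR with
    conditional F-statistics and MR-Lasso, Cox proportional-hazards and
    Kaplan-Meier survival analysis of an incident phenotype derived from
    diagnosis codes, principal-component-based multiplicity correction,
    k-means clustering of correlated exposures, and an explicit
    causal-call triage. Ships simulators for two-sample GWAS summary
    statistics with known pleiotropy structure and for survival cohorts
    with a factor-correlated metabolite panel, so every stage can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    survival,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
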