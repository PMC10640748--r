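Package: mrphewas
Title: Phenome-Wide Two-Sample Mendelian Randomization Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for phenome-wide two-sample Mendelian randomization
    (MR-PheWAS) against a binary disease outcome: GWAS summary-statistic
    input/output and allele harmonisation, LD clumping and proxy search
    against a reference genotype panel, Wald-ratio / inverse-variance-weighted
    / MR-Egger / maximum-likelihood causal estimators with heterogeneity and
    pleiotropy diagnostics, spectral-decomposition multiple-testing
    correction, reverse-direction MR, two-step mediation through intermediate
    traits, approximate-Bayes-factor colocalization, and a summary-statistic
    conditional scan for secondary association signals. A synthetic-data
    module simulates two-sample GWAS cohorts with known causal structure so
    that every stage can be validated end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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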