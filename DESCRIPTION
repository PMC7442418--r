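Package: mrscreen
Title: Two-Sample Mendelian Randomization Screening with GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for screening many continuous exposures against a
    binary disease outcome by two-sample Mendelian randomization from GWAS
    summary statistics. Covers instrument selection (genome-wide significance
    filtering, greedy LD clumping, F-statistic screening), allele
    harmonization with palindromic-variant policies, five causal estimators
    (Wald ratio, fixed-effects inverse-variance weighting, profile maximum
    likelihood, weighted median, weighted mode), MR-Egger regression for
    directional pleiotropy, leave-one-out driver-SNP detection, Bonferroni
    multiplicity classification, a priori power for binary outcomes, and a
    seeded generator of synthetic summary statistics with known causal
    structure for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'accessors.R'
    'gwas_io.R'
    'instruments.R'
    'estimators.R'
    'sensitivity.R'
    'simulate.R'
    'power.R'
    'study.R'
    'utils.R'
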