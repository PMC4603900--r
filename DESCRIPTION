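Package: snpindex
Title: Prognostic Index from Germline SNP Panels in Survival Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates a genotype-score prognostic index for
    survival cohorts genotyped on a small panel of biallelic SNPs, as used
    in prognostic studies of surgically resected early-stage non-small cell
    lung cancer. Provides per-SNP adjusted Cox proportional-hazards
    association analysis under additive, dominant and recessive genetic
    models, Hardy-Weinberg and genotype-distribution tests, Kaplan-Meier and
    log-rank inference, genotype scoring (1/2/3) with a summed index and an
    approximate-tertile cutoff, risk-group comparison with covariate
    adjustment, and a calibrated synthetic-cohort generator with
    proportional-hazards event times and administrative censoring for
    validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
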