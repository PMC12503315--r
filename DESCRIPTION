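Package: ergscreen
Title: Quality Control and Statistical Screening of Mouse Electroretinography Cohorts
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for large electroretinography (ERG) screens of
    knockout mouse strains. Provides waveform input/output and validation,
    baseline offset correction, inter-trial mean-absolute-deviation consistency
    filtering, trial averaging, component amplitude extraction (scotopic a-, b-,
    c- and FO-like waves; photopic a- and b-waves), wildtype-referenced
    extreme-value filtering, soft-window temporal weighting of control animals,
    weighted genotype ANOVA with percentage effect sizes, between-eye concordance
    hit calling, sexual-dimorphism tests, and a fully seeded synthetic cohort
    generator with ground-truth bookkeeping for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
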