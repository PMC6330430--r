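Package: hcscreen
Title: Guideline-Based Screening for Hereditary Cancer Syndromes from Family History
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An auditable rule engine that matches structured personal and
    family cancer histories one-to-one against published genetic-testing
    criteria for BRCA-related hereditary breast and ovarian cancer, Lynch
    syndrome, and polyposis syndromes. Provides a controlled-label pedigree
    data model with kinship algebra (degree, lineage, generation,
    re-rooting), deterministic normalization of imprecise ages and free-text
    cancer types, extraction of independent validation events, modeled
    low-risk case construction, confusion-matrix accuracy statistics with
    exact (Clopper-Pearson) binomial confidence intervals, one-sample
    proportion sample-size planning, and a seeded synthetic pedigree
    generator so the full validation pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
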