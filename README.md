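# hcscreen

Guideline-based screening for hereditary cancer syndromes from structured
family history, plus the statistics needed to validate such a screen.

## What it does, and for whom

Roughly 5–10% of cancers arise from hereditary cancer syndromes, yet most
people who meet published genetic-testing criteria — for BRCA-related
hereditary breast and ovarian cancer (HBOC), Lynch syndrome, and polyposis
syndromes — are never referred for testing. `hcscreen` is for clinical
informaticists and researchers building or evaluating automated
family-history screens. It provides:

* a **pedigree data model** over controlled kinship labels, with the
  kinship algebra (consanguinity degree, lineage, generation offset,
  re-rooting) the criteria depend on;
* a **rule engine** that matches a history one-to-one against the
  enumerated BRCA-related, Lynch-syndrome, and polyposis testing criteria
  (V2.2017 semantics), reporting *every* fulfilled criterion with the
  relatives that justify it;
* **validation machinery**: independent-event extraction, modeled
  low-risk case construction, confusion-matrix accuracy statistics with
  exact binomial confidence intervals, and sample-size planning;
* a **seeded synthetic cohort generator**, so the entire validation
  pipeline runs end-to-end with no external data.

The statistical core is the standard screen-validation panel. With A/B/C/D
the true-positive/false-positive/false-negative/true-negative event counts:

    sensitivity = A/(A+C)    specificity = D/(D+B)    accuracy = (A+D)/(A+B+C+D)

each with a Clopper–Pearson exact 95% interval from the beta-quantile
formulation, lower = qbeta(α/2, x, n−x+1), upper = qbeta(1−α/2, x+1, n−x);
and the one-sample proportion sample size n = (z₁₋α/₂ + z₁₋β)² p(1−p)/δ².

## A worked example

A 40-something proband with early-decade breast cancer, an ovarian cancer
in her mother, and an early breast cancer in a maternal aunt:

```r
library(hcscreen)

p <- pedigree(
  proband = family_member("self", sex = "female",
    diagnoses = list(normalize_cancer("breast", age_record("EARLY_DECADE", 40)))),
  members = list(
    family_member("mother", diagnoses = list(diagnosis("ovarian", 62))),
    family_member("maternal aunt", diagnoses = list(diagnosis("breast", 48))),
    family_member("father"),
    family_member("sister")),
  ethnicities = "Caucasian")

evaluate_pedigree(p)
#> <screening report> MEETS criteria
#>   fulfilled: B10, B11, B18, B2, B4
#>   genetic screening should be considered at this time
```

The "early 40s" age imputes to 42, so the proband meets the breast ≤ 45
criterion (B2) and, through her own breast cancer, the
close-relative-breast (B4), relative-breast-under-50 (B10) and
relative-ovarian (B11) criteria; B18 records that an affected relative
would also qualify as an index case in their own right. The fixed
recommendation string is the screen's positive output; the per-criterion
events (`evaluate_pedigree(p)$events`) name the contributing relatives.

The validation statistics reproduce a published-style accuracy panel from
a 2×2 table of expert-vs-engine event calls:

```r
panel <- accuracy_panel(confusion_counts(382, 2, 0, 381))
panel$specificity
#> 381/383 = 99.48% (98.13-99.94% CI at 95%)
panel$accuracy
#> 763/765 = 99.74% (99.06-99.97% CI at 95%)
```

A command-line wrapper ships in `inst/cli/hcscreen` with subcommands
`evaluate`, `events`, `model-low-risk`, `validate`, and `simulate`.

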