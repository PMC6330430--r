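---
title: "The criteria engine: model, conventions, and validation machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The criteria engine: model, conventions, and validation machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcscreen)
```

## The problem

A large majority of people who meet published genetic-testing criteria for
hereditary cancer syndromes — BRCA-related hereditary breast and ovarian
cancer (HBOC), Lynch syndrome, and the polyposis syndromes — are never
identified in routine care. Screening tools address this by matching a
personal and family cancer history against the criteria automatically.
`hcscreen` implements such a screen as an *auditable rule engine*: every
criterion is an explicit, testable predicate over a structured pedigree, the
engine reports *every* fulfilled criterion (not a first match), and each
match carries the relatives that justify it. The package also implements the
machinery needed to validate such a screen against expert pedigree review:
independent-event extraction, modeled low-risk case construction,
confusion-matrix statistics with exact binomial confidence intervals, and a
seeded synthetic cohort generator so the whole pipeline runs with no
external data.

## The pedigree model

A family history is recorded the way intake questionnaires record it:
relatives are identified by controlled kinship labels relative to the
proband ("mother", "maternal aunt", "paternal first cousin"), not by an
explicit family graph. Each label determines, by table lookup:

* **degree** — standard consanguinity degree 1–3 (first-degree: parents,
  full siblings, children; second: grandparents, aunts/uncles,
  half-siblings, nieces/nephews, grandchildren; third: great-grandparents,
  great-aunts/-uncles, first cousins);
* **lineage** — maternal or paternal bloodline; full siblings, children and
  grandchildren share both parental bloodlines and count on either side;
  half-siblings must be side-tagged, because their lineage is otherwise
  undefined;
* **generation offset** — proband 0, parents +1, grandparents +2,
  children −1.

The label vocabulary is capped at degree 3 by construction: the screen's
evidence base is the standard three-generation pedigree, and positions
beyond it are not representable. Lineal positions (mother, the four
grandparents, ...) are unique slots; collateral labels may repeat (two
maternal aunts are two people).

**Close blood relatives** of the proband on one side are all members of
degree 1–3 whose lineage is that side or "both". The proband is never a
member of this set, but the proband's own diagnoses can support
family-pattern clauses where a criterion counts cancers "in the family".

### Re-rooting and the family-history mirror

Several criteria are family-history-only: they apply when a first- or
second-degree relative *would themselves* meet a personal-history criterion.
The engine implements this by *re-rooting*: the pedigree is re-expressed
from the relative's point of view, with every original person re-labeled by
kinship arithmetic over (up, down, side, half) path coordinates, and the
personal-history criteria are evaluated with the relative as index case.

Label-only histories cannot always pin down the exact topology, so
re-rooting uses three documented conventions:

1. **Ambiguity resolves away from the root.** A niece relative to a sibling
   root could be the root's own daughter or another sibling's daughter; the
   engine assumes the connection does *not* pass through the root (niece,
   the more distant reading). This under-fires rather than over-fires
   criteria.
2. **Side tags are bloodline identifiers.** After re-rooting, a "maternal"
   tag means "the same bloodline that was maternal for the original
   proband", not literally the root's mother's side. This preserves the
   rule that counting clauses never combine relatives across bloodlines.
3. **Forced sides go maternal.** Members of both bloodlines (siblings,
   children) that must take a single side tag after re-rooting are tagged
   maternal, deterministically.

Positions that fall outside the vocabulary after re-rooting (e.g. a
great-niece) are dropped; dropped members can only prevent, never cause, a
criterion match, which again errs toward under-firing.

## Normalization

Recorded histories are messy in two specific ways the engine must handle
deterministically:

* **Imprecise ages.** "Early 70s" imputes to 72, "late 70s" to 78, "70s" to
  75 (decade start + 2/8/5; offsets configurable). Unknown ages satisfy
  only "at any age" clauses, never age-bounded ones — the conservative
  reading used in pedigree review, which never invents an age.
* **Free-text cancer types.** A synonym table maps recorded labels onto a
  canonical vocabulary of 36 named types; anything unmapped becomes
  "other/unspecified", never an error. The full 36-type list of the
  original intake tool is not published; the shipped vocabulary is a
  reconstruction from the types the validation cohort exercised plus the
  ovarian-equivalent and Lynch-related sets, padded with common referral
  types, and is extensible at run time.
* **Prostate cancer** without grading information is assumed high-risk
  (Gleason score > 7), because pedigrees rarely record aggressivity.

Breast criteria include invasive disease, DCIS, and triple-negative
subtypes; triple-negative additionally feeds its own age-bounded criterion.
"Ovarian carcinoma" always includes fallopian tube and primary peritoneal
cancers.

## The criteria and their conventions

The registry implements the enumerated criterion set: 19 BRCA-related rules
(known family mutation; the personal breast-cancer rules at ≤45/≤50/≤60;
family-pattern rules; personal ovarian-equivalent, male breast, prostate
and pancreatic rules; the first-/second-degree mirror; and the
third-degree-relative breast/ovarian cluster), 6 Lynch rules (known
mutation; the first-degree-relative colorectal/endometrial rules; the
two-relative and three-relative clusters; Amsterdam II), and 3 polyposis
rules. The full guideline sets contain 25/16/3 criteria; the remainder
involve tumor/somatic test results or mutation-probability models, are out
of scope here, and the registry is data-driven so additional rules can be
added without engine changes. The three polyposis rules (known APC/MUTYH
mutation; personal or first-degree-relative cumulative adenoma count at or
above a threshold, default 10) are reconstructions: the underlying rules
are not printed anywhere, and the validation cohort contained no
polyposis-qualifying history to constrain them.

Decisions that the printed criteria leave open, and how this package takes
them:

* **Inequality glyphs.** The printed tables show "> 1 / > 2 / > 3" where
  the guideline semantics are at-least counts; the engine implements ≥1/≥2/≥3.
  Under a strictly-greater reading, a single-affected-relative rule could
  never fire on the single-relative histories the criteria are built for.
* **Age bounds.** Breast-criteria bounds are inclusive (≤45/≤50/≤60),
  matching the guideline wording "diagnosed at or under"; the Lynch and
  Amsterdam "before age 50" bounds are strict. Both choices are
  configuration-exposed (`engine_config(brca_age_inclusive = )`).
* **Counting semantics.** For clauses of the form "index case + k close
  relatives", the counted relatives must share one side of the family
  ("both"-lineage members count on either side); the index person never
  counts among their own supporters; distinct *people* are counted, not
  distinct tumors — except the additional-breast-primary rule, which is
  explicitly about two primaries in one person.
* **Limited/unknown family history** is operationalized as: both sides
  report fewer than 2 relatives beyond the parents (threshold
  configurable), or the family-size answer declares unknown structure.
* **Synchronous/metachronous second cancers** (Lynch) require the *same*
  first-degree relative to carry the colorectal/endometrial diagnosis and a
  second Lynch-related primary (flagged, or simply present as a second
  primary).
* **Known-mutation rules** fire on a finding in any blood relative of
  degree ≤ 3, or the proband.
* **Ashkenazi ethnicity** is family-level: the ethnicity rule fires for a
  personal breast cancer or, mirrored, for an affected first-/second-degree
  relative in the same family.

Every match is emitted as a *criterion event* carrying the criterion id,
the index person, the side used, and the contributing members; re-running
the engine on just those people reproduces the match (events are
self-certifying, and the test suite asserts this on random pedigrees).

## Validation machinery

The validation design treats the *criterion*, not the pedigree, as the unit
of analysis:

* A qualifying pedigree contributes one **criterion event** per distinct
  fulfilled criterion; mirror matches are keyed by the mirrored
  personal-history criterion, so two relatives mirroring the same rule
  contribute one event, while mirrors of different rules contribute one
  each.
* A non-qualifying pedigree contributes one **single-history event** per
  (person, diagnosis) — polyp findings included — plus one **combination
  event** per side of the family carrying two or more single histories
  (a per-pair mode is configurable; identical groupings arising on both
  sides are emitted once), or a single **no-family-history event** when
  nothing remains.
* **Modeled low-risk cases** are built from qualifying pedigrees by
  removing qualifying events: `model_low_risk()` greedily deletes the
  history item whose removal extinguishes the most currently fulfilled
  criteria (ties: items that contribute to a fulfilled criterion first,
  then youngest age at diagnosis, then member order) until nothing fires,
  preserving all remaining history verbatim. The expert process it models
  is not algorithmically specified; greediness with fixed tie-breaks was
  chosen for determinism, and the operation is idempotent.

Each event can be *re-entered* into the engine as its own minimal history
(the one-to-one entry protocol): criterion events as their contributing
members, single/combination events as reconstructed minimal pedigrees that
preserve person identity, family-level ethnicity and the declared family
sizes — the latter matters because the limited-family-history rule is
deliberately anti-monotone in family size.

Paired expert/engine labels then feed a standard 2×2 screen-validation
panel: sensitivity A/(A+C), specificity D/(D+B), accuracy (A+D)/total, each
with a Clopper–Pearson exact interval from the beta-quantile formulation
(`qbeta(α/2, x, n−x+1)`, `qbeta(1−α/2, x+1, n−x)`). The exact method is the
default because it reproduces published screening-validation bounds
exactly (for x = n the lower bound is (α/2)^(1/n)); Wald/Wilson
approximations are deliberately not offered as defaults. Sample-size
planning uses the one-sample normal-approximation formula
n = (z₁₋α/₂ + z₁₋β)² p(1−p)/δ², rounded up; at p = 0.90, δ = 0.05, α = 0.05
and 90% power this gives 379 events per group.

## The synthetic cohort generator

`sim_config()` / `generate_cohort()` emulate a referral-population
validation cohort: all-female probands, the ethnicity mix of a US referral
population (74% Caucasian, ~9% Ashkenazi Jewish, ...), ~28% of high-risk
probands with a personal history, a relative-level background cancer mix
proportional to the cancer-type margins observed in low-risk referral
events (female breast, lung, colon, skin, prostate and melanoma most
frequent), ~16% of relatives carrying a background diagnosis, and
three-generation structures (parents and grandparents always reported,
Poisson counts of siblings, children, aunts/uncles and cousins) sized so
that second-degree histories dominate. High-risk pedigrees are produced by
injecting one sampled *motif* — early breast, same-side breast cluster,
ovarian carcinoma, male breast, Ashkenazi + breast, early colorectal in a
first-degree relative, a same-side Lynch cluster, or a known mutation —
with weights echoing the observed criterion mix, then verifying the engine
fires (bounded retries). Low-risk pedigrees are background draws passed
through `model_low_risk()`. A configurable fraction (default 30%) of
relatives' ages are re-encoded as decade/early/late-decade records to
exercise the imputation path. Polyp incidence defaults to zero, matching a
cohort in which no polyposis history was observed.

Under these defaults a 197 + 123 cohort yields event totals within about a
quarter of the published group totals (382 high-risk and 383 low-risk
events). Everything is driven by a single mandatory seed: a fixed (seed,
config) pair reproduces the cohort byte-for-byte.

Two things the generator deliberately does **not** model: gold labels come
from the same criteria semantics the engine implements, so cohort round
trips validate the *plumbing* (event extraction, modeling, re-entry,
statistics), not criteria correctness — that is validated separately
against an independent brute-force clause-enumeration oracle and
hand-checked worked examples in the test suite; and it has no
population-genetics realism (no penetrance, ascertainment or survival
modeling). Discordance is therefore structurally impossible on an
unperturbed cohort (B = C = 0 by construction); the `perturb_ages()`
operator exists to inject threshold-crossing discordance for non-trivial
panels.

## Numerical and degenerate-input choices

* Evaluation is pure and deterministic; no randomness anywhere in the
  engine.
* Unknown ages: excluded from every age-bounded comparison (never imputed
  to a default).
* Zero denominators in the accuracy panel yield "undefined" (`NULL`), not 0.
* Empty pedigrees are valid and meet nothing; an empty history after
  low-risk modeling is a valid "no family history" case.
* The simulator's retry budget (default 30) bounds motif injection; an
  infeasible configuration (e.g. all incidences zero with a motif that
  needs an affected relative) fails loudly rather than looping.
* Problem sizes in the shipped tests: 1000 random pedigrees (≤ 8 members)
  for oracle equivalence, 1000 for the monotonicity property, a 197 + 123
  cohort for the end-to-end round trip, and 10,000 replicates × 3
  proportions at n = 383 for interval coverage — sizes chosen to exercise
  the properties thoroughly while keeping a full check run in minutes.

## Known limitations

* Criteria involving tumor pathology or somatic testing, and
  mutation-probability models, are out of scope by design.
* The polyposis rules and parts of the cancer vocabulary are
  reconstructions (flagged above).
* Kinship is label algebra, not a graph: consanguinity loops, adoption and
  unknown parentage are not representable, and re-rooting resolves
  topological ambiguity by convention (documented above) rather than by
  asking for more structure.
* The mirror criterion is evaluated only at first-/second-degree relatives;
  third-degree relatives participate only through their dedicated cluster
  criterion.
* Passing synthetic-cohort tests demonstrates internal consistency on
  histories shaped like the emulated referral population; it does not, by
  itself, demonstrate accuracy on real-world pedigrees, which vary in ways
  (recall bias, missing sides, free-text noise) the generator does not
  model.
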