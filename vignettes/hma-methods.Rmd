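---
title: "Methods: rule encoding, scoring and study simulation in hmaguide"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule encoding, scoring and study simulation in hmaguide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmaguide)
```

`hmaguide` is the logic layer of a guideline-based hypertension
self-management system: rules as data, an engine that applies them, and
the validation machinery around both. This vignette records the model,
the parameters that matter, and the design decisions taken where the
source material left the design open.

## The knowledge base as data

All clinical content lives in one YAML file
(`inst/extdata/hma_kb.yaml`), never in code. It contains:

* **8 target-setting rule groups**, one per intervention item. A group
  is a list of branches; each branch has a profile condition (a
  conjunction of field comparisons, with a final catch-all), one or more
  criteria (measure, comparator, threshold or formula, unit), and a
  target sentence id. Branches are tried in order and the first match
  fires, so every group is exhaustive by construction; `validate_kb()`
  flags groups whose final branch is conditional.
* **20 evaluation rules** mapping (item, fired target branch,
  maintain/modify or stress level) to an evaluation sentence and a
  recommendation template.
* **17 base recommendation templates**: maintenance + modification for
  each of the seven non-stress items, plus three stress-level templates.
  Three expert-contributed detail recommendations (daily alcohol
  recording, sodium-specific advice, "get advice from a professional")
  ride along as `detail_options`, not as base templates.

Thresholds may be formulas over profile fields (the body-weight bound is
`25 * height^2`); formula evaluation is restricted to arithmetic on
whitelisted field names so the file remains data. There is no
JSON-Schema engine behind the file: the schema is enforced in two code
layers, structural checks at load time (missing sections or fields fail
with the offending entry named) and semantic invariants in
`validate_kb()` (counts, uniqueness, referential integrity,
exhaustiveness, dictionary coverage), which reports violations instead
of raising so that deliberately broken knowledge bases can be examined.

### The T/E/R id scheme

Only the waist-circumference ids are fixed by the published worked
example (targets T7/T8, evaluations E19/E20, recommendations R19/R20);
the remaining ids and the composition of the 20 evaluation rules are not
enumerated in the source material, which gives only the counts (8 rule
groups, 20 rules, 17 templates). Seven non-stress items with a
maintain/modify pair plus three stress levels yield 17 rules, so three
evaluation rules beyond the one-per-template minimum must exist. The
package's reconstruction resolves this by branch-splitting the two items
whose *target* depends on the profile and whose evaluation sentences are
therefore branch-specific: blood pressure carries four rules (each
target branch × maintain/modify, the pairs sharing one maintenance and
one modification template) and alcohol three (a shared maintenance rule
plus one modification rule per sex/weight branch, sharing the
modification template). With items ordered blood pressure, sodium,
weight, alcohol, smoking, stress, exercise, waist, the waist rules land
exactly at E19/E20 → R19/R20. Target sentences are numbered T1–T9 in
rule-table row order, the waist branches taking T7 (male) and T8
(female). This is a reconstruction, marked as such here; any other
scheme consistent with the printed ids would behave identically, since
the engine routes through ids, not positions.

Recommendation texts other than the published waist-modification
sentences are composed in the same three-part register and are marked
`provenance: composed` in the knowledge base, versus `verbatim` for the
deployed app text.

## The rules engine

`set_targets()` resolves all eight groups for a profile;
`evaluate_item()` compares measurements against the fired branch;
`recommend_all()` composes one three-part recommendation per evaluable
item. Decisions fixed here:

* **Comparators are applied strictly as printed.** `<` excludes
  equality (a female waist of 88 cm is off-target; 1 cigarette/day is
  off-target because the target is `< 1`), `≤` includes it (BEPSI-K 1.6
  and 14 glasses/week are on-target). Age 60 falls in the `≥ 60`
  branch.
* **Conjunction items.** Alcohol is on-target only when both the daily
  and the weekly bound hold; exercise only when frequency, duration and
  intensity all exceed their bounds (intensity is coded ordinally,
  light = 1 < moderate = 2 < vigorous = 3, so "more than moderate" means
  vigorous). No scalar signed difference is reported for conjunctions.
* **Missing data make an item unevaluable, never off-target.** A
  missing sub-measurement of exercise skips the whole item and is
  reported in the `skipped` attribute.
* **Diastolic pressure is recorded but never ruled on** — the encoded
  targets are systolic only.
* **Number rendering**: at most one decimal, integers without a decimal
  point, units appended; identical inputs yield byte-identical text.

Two rule-table conflicts in the source material are resolved in favour
of the table titled as the rule set: exercise uses the strict
conjunction (> 4 times/week, > 60 min, above moderate) rather than the
softer intervention-table phrasing (30–60 min, 4–7 times/week), and
stress uses the BEPSI-K ≤ 1.6 bound rather than the
susceptibility-scale < 30 criterion, which is retained only as a comment
in the knowledge file and is not implemented.

## Questionnaire scoring

MMS totals are plain item sums over adherent-coded 0/1 answers;
reverse-keying happens once at ingestion (`mms_recode()`). The
motivation/knowledge factor partition is not published; the default
({1, 2, 6} / {3, 4, 5}) is declared in the knowledge-base config as
data, not asserted as psychometric truth. The 12 diet items are modeled
as anonymous binary behaviors (the rules depend only on the total, and
whether the deployed items were binary is unstated — binary is assumed).
BEPSI-K is the item mean on 1–5, consistent with the 1.6 bound. Stress
levels use cutpoints low ≤ 1.6 < moderate ≤ 2.8 < high; only the 1.6
bound is sourced, 2.8 is a configurable default chosen to split the
remaining range roughly in half. Perceived usefulness is the mean of six
item means (reported to one decimal); satisfaction is deliberately
per-function, never pooled. `cronbach_alpha()` is a utility only.

## Records and adherence

Persistence is a single JSON document per patient; CSV export mirrors
the "send data" use case with file transport instead of e-mail. A dose
counts as taken when an intake record for the same drug and slot is
marked taken within a grace window of ±6 h (configurable) — the source
never defines lateness. Adherence pools across drugs by default with a
per-drug breakdown, since the deployed computation granularity is
unstated. Timestamps are timezone-naive local times (single-user device
semantics), ISO-8601 on disk. Ties in the blood-pressure log are broken
by insertion order, later-inserted treated as newer.

## Knowledge-base validation by branch coverage

A decision node is either a target rule group with ≥ 2 branches (the
default knowledge base has 3: blood pressure, alcohol, waist) or an
item's evaluation branch point (8 nodes: maintain/modify for seven
items, the three stress levels for stress) — 11 nodes, 23 branches in
all. `build_covering_suite()` builds candidate scenarios from three
canonical profiles (older healthy male, younger female, older comorbid
male under 60 kg — together they reach every profile-dependent target
branch) crossed with all-on-target and all-off-target measurement
patterns cycling the stress levels, then adds scenarios greedily by
uncovered-branch gain until coverage is complete. Witness values sit one
unit inside/outside each resolved threshold (87/89 cm around a female
waist target of 88) for human readability. For the default knowledge
base the suite has 3 scenarios — comfortably within the seven used in
the original expert evaluation, and at the information-theoretic lower
bound set by the three-branch stress node. An unreachable branch
(contradictory knowledge base) is reported by name.

## Study simulation

The deployment study's paired pre/post adherence scores are not
published, so the package simulates cohorts at the reported margins
(pre mean 4.2, SD 1.3; post 5.2, SD 1.1; n = 29 completers of 38
enrolled). Each MMS total is modeled as the sum of 6 exchangeable
Bernoulli items: a beta-binomial whose mean is matched exactly and whose
item-level intraclass correlation is calibrated to the requested SD
(both study SDs are overdispersed relative to the binomial, so the
calibration is feasible; an SD below the binomial SD at that mean errors
with the feasible range, except the degenerate SD = 0 constant case).
Pairing uses a Gaussian copula on a shared latent adherence propensity
with correlation `rho`; the pre/post pairing correlation is not
published, so `rho` is an explicit free parameter defaulting to 0.5.
Attrition (38 → 29) is treated as missing-at-random: the generator draws
completers directly, and the known caveat that dropouts may have been
low adherers is a documented limitation, not modeled causally.

The Wilcoxon signed-rank test drops zero differences (the common
statistical-package default, rather than the zero-retaining variant),
assigns midranks to ties, and computes the two-sided p exactly by
enumerating all sign patterns of the observed (mid)ranks when the
number of nonzero differences is at most 12 — a cutover balancing
runtime against accuracy, configurable per call — and otherwise by
normal approximation with the usual tie correction and no continuity
correction. The exact branch is verified in the tests against an
independent brute-force enumeration and, for tie-free cases, against
`stats::wilcox.test`; the reference implementation is used only as an
oracle, never as the engine.

## What the synthetic data does and does not show

The generators reproduce the *stated margins* of the study conditions:
score support, means, SDs, cohort size, attrition counts. They do not
reproduce per-item MMS response patterns, longitudinal measurement
trajectories, realistic missingness, or any correlation between
lifestyle measurements and adherence — none of which are published.
Passing tests therefore demonstrate that the engine and statistics are
correct on data with the study's marginal properties, not that the
deployed system's patient-level results are recovered; in particular the
study's P = .001 on the real 29 pairs is not a reproduction target,
though simulated cohorts at the same margins are significant in the
median across seeds.

## Problem sizes and runtime choices

Test and simulation sizes are chosen to keep the whole suite fast while
leaving no property under-exercised: exhaustive enumeration where the
space is tiny (all 64 MMS vectors, all sign patterns at n ≤ 10),
a few hundred random cases for engine/oracle agreement and rule-group
exhaustiveness, 200 seeds for the n = 29 power check, n = 10⁵ for
cohort moment recovery (tolerance 3·SD/√n). The acceptance script uses
n = 10,000 for the cohort mean, matching a sampling error well inside
one-decimal reporting.

## Known limitations

* The data dictionary covers every field the rules consume; the
  deployed system's full 41-item dictionary was never published, so no
  cardinality claim is made.
* Recommendation texts other than the published waist sentences are
  paraphrases in the same register, flagged as such in the knowledge
  base.
* The engine encodes self-management knowledge only: no diagnosis, no
  prescribing, no drug-interaction logic; the bundled medication
  "education" file is clearly-labeled synthetic sample content standing
  where the deployed system queried a live drug-information service.
* Localization: sentences are English; the knowledge file is structured
  so a translated file can be dropped in (the deployed system was
  Korean).
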