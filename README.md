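# hmaguide

Guideline-based decision support for hypertension self-management.

Patients with hypertension manage most of their risk outside the clinic:
blood pressure, sodium intake, body weight, waist circumference,
exercise, alcohol, smoking and stress. Clinical practice guidelines state
numeric goals for each of these, but as prose. `hmaguide` encodes that
knowledge as data — a machine-readable knowledge base of target-setting
rules and recommendation templates — and provides the engine that turns a
patient profile and self-reported measurements into tailored, three-part
advice, plus the tooling to validate the knowledge base and simulate a
pre/post adherence study. It is aimed at researchers and developers of
rule-based mobile or nursing decision-support systems who need the logic
layer to be testable and inspectable, independent of any app UI.

## The model

**Target setting.** Eight rule groups, one per intervention item, map a
profile (sex, age, height, weight, diabetes and/or chronic renal disease)
to numeric goals:

| Item | Rule |
|---|---|
| Systolic BP | age ≥ 60 without underlying disease → < 150 mmHg; else < 140 mmHg |
| Diet behavior | score < 5 (12-item questionnaire total) |
| Body weight | weight < 25 × height² (BMI < 25 kg/m²) |
| Alcohol | male and weight ≥ 60 kg → ≤ 2 glasses/day and ≤ 14/week; else ≤ 1/day and ≤ 9/week |
| Smoking | < 1 cigarette/day |
| Stress | BEPSI-K mean score ≤ 1.6 |
| Waist | male → < 102 cm; else < 88 cm |
| Exercise | > 4 sessions/week **and** > 60 min/session **and** > moderate intensity |

**Evaluation and recommendation.** Twenty evaluation rules compare
measurements with the resolved targets and select among 17 base
recommendation templates (one maintenance + one modification per
non-stress item, three stress levels). Every recommendation has a fixed
three-part structure: target sentence, evaluation result (measured value
and signed difference from target), recommendation text.

**Instruments.** The Modified Morisky Scale (6 yes/no items, total 0–6,
motivation/knowledge subscales), the 12-item diet-behavior questionnaire
(sodium proxy) and BEPSI-K (5 Likert items, mean score 1–5).

**Validation.** Decision nodes (target branch points and evaluation
branch points) are enumerated mechanically from the knowledge base;
`build_covering_suite()` constructs a small scenario suite in which every
branch of every node fires at least once. Pre/post adherence studies are
simulated with a calibrated beta-binomial cohort generator and tested
with a Wilcoxon signed-rank test (exact sign-pattern enumeration at small
n, normal approximation with tie correction otherwise).

## Worked example

```r
library(hmaguide)
kb <- load_default_kb()
prof <- patient_profile("female", age = 50, height = 1.60, weight = 60)
m <- measurements(systolic_bp = 152, diastolic_bp = 88, waist = 92,
                  bepsik_score = 1.4, cigarettes_per_day = 0)
recommend_all(prof, m, kb)
```

```
<hma_recommendation_set> 4 recommendation(s)

Your target systolic blood pressure is below 140 mmHg. Your systolic blood
pressure is 152 mmHg, 12 mmHg over the target. Lowering systolic blood
pressure below 140 mmHg reduces the risk of cardiovascular complications.
Take your medication as prescribed, reduce sodium intake, and measure your
blood pressure regularly.

Your target is fewer than 1 cigarette per day. You smoke 0 cigarettes per
day, which meets your target. You are meeting the smoking target. Staying
smoke-free helps keep your blood pressure down.

Your target stress score (BEPSI-K) is at most 1.6. Your BEPSI-K stress
score is 1.4, indicating a low stress level. Your stress level is low.
Keep using your current coping strategies.

Your target waist circumference is 88 cm. Your waist circumference is
92 cm, 4 cm over the target. For a hypertension patient, maintaining the
proper waist circumference is necessary to lower blood pressure. Reduce
your waist circumference to 88 cm.

skipped (missing measurements): sodium_intake, body_weight, alcohol, exercise
```

Reading the output: the patient is a 50-year-old woman, so her systolic
target takes the under-60 branch (140 mmHg) and her waist target the
female branch (88 cm). Each paragraph is one tailored recommendation in
the fixed order target → evaluation → advice; items without measurements
(here diet, weight, alcohol, exercise) are skipped and listed rather than
guessed. Her 92 cm waist is 4 cm over target, so the modification
template fires; smoking and stress are on target, so their
maintenance/low templates fire.

The same engine is available from the shell via the `hma` script in
`inst/cli/` (`hma recommend --profile p.json --measurements m.json`,
`hma kb validate`, `hma score mms --answers 1,1,1,1,1,1`, ...).

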