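Package: hmaguide
Title: Guideline-Based Decision Support for Hypertension Self-Management
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A rule-based decision-support engine for hypertension
    self-management. Encodes clinical-practice-guideline knowledge as a
    machine-readable knowledge base of target-setting rules, evaluation
    rules and three-part tailored recommendation templates covering blood
    pressure and seven lifestyle items; scores the Modified Morisky Scale,
    a 12-item diet-behavior questionnaire and the BEPSI-K stress
    instrument; tracks blood-pressure and medication-intake records with
    adherence rates and reminders; and validates the knowledge base by
    scenario-based decision-node branch coverage. Includes a synthetic
    pre/post cohort generator and a Wilcoxon signed-rank test with exact
    small-sample enumeration for desk-scale study simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
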