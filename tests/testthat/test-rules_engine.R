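test_that("target setting resolves every rule-table constant", {
  kb <- kb_default
  thr <- function(prof, item) {
    e <- set_targets(prof, kb)$entries[[item]]
    vapply(e$criteria, `[[`, numeric(1), "threshold")
  }
  young <- patient_profile("male", 45, 1.75, 70)
  old_healthy <- patient_profile("female", 65, 1.60, 55)
  old_diabetic <- patient_profile("male", 65, 1.70, 80, has_diabetes = TRUE)
  exactly60 <- patient_profile("male", 60, 1.80, 75)

  expect_equal(thr(young, "blood_pressure"), 140)
  expect_equal(thr(old_healthy, "blood_pressure"), 150)
  expect_equal(thr(old_diabetic, "blood_pressure"), 140)
  expect_equal(thr(exactly60, "blood_pressure"), 150)  # >=60 as printed

  expect_equal(thr(young, "sodium_intake"), 5)
  expect_equal(thr(young, "body_weight"), 25 * 1.75^2)
  expect_equal(thr(young, "alcohol"), c(2, 14))        # male, >=60 kg
  expect_equal(thr(old_healthy, "alcohol"), c(1, 9))   # female
  light_male <- patient_profile("male", 40, 1.70, 55)
  expect_equal(thr(light_male, "alcohol"), c(1, 9))    # male under 60 kg
  expect_equal(thr(young, "smoking"), 1)
  expect_equal(thr(young, "stress"), 1.6)
  expect_equal(thr(young, "waist_circumference"), 102)
  expect_equal(thr(old_healthy, "waist_circumference"), 88)
  expect_equal(thr(young, "exercise"), c(4, 60, 2))
})

test_that("waist evaluation reproduces the female 92 cm worked example", {
  prof <- patient_profile("female", 50, 1.60, 60)
  ev <- evaluate_item("waist_circumference", prof, measurements(waist = 92),
                      kb_default)
  expect_equal(ev$status, "off_target")
  expect_equal(ev$signed_difference, 4)
  expect_equal(ev$target_sentence_id, "T8")
  expect_equal(ev$evaluation_sentence_id, "E20")
  expect_equal(ev$recommendation_id, "R20")
  expect_equal(ev$target_sentence, "Your target waist circumference is 88 cm")
  expect_equal(ev$evaluation_sentence,
               "Your waist circumference is 92 cm, 4 cm over the target")

  on <- evaluate_item("waist_circumference", prof, measurements(waist = 87),
                      kb_default)
  expect_equal(on$status, "on_target")
  # strict comparator: the bound itself is off-target
  at <- evaluate_item("waist_circumference", prof, measurements(waist = 88),
                      kb_default)
  expect_equal(at$status, "off_target")
})

test_that("systolic evaluation depends on the age/comorbidity branch", {
  m <- measurements(systolic_bp = 145, diastolic_bp = 80)
  mid <- evaluate_item("blood_pressure",
                       patient_profile("male", 45, 1.75, 70), m, kb_default)
  old <- evaluate_item("blood_pressure",
                       patient_profile("male", 65, 1.75, 70), m, kb_default)
  expect_equal(mid$status, "off_target")   # target < 140
  expect_equal(old$status, "on_target")    # target < 150
  old_crd <- evaluate_item("blood_pressure",
                           patient_profile("male", 65, 1.75, 70,
                                           has_chronic_renal_disease = TRUE),
                           m, kb_default)
  expect_equal(old_crd$status, "off_target")
})

test_that("conjunction items require every condition; missing parts error", {
  prof <- patient_profile("male", 40, 1.80, 80)
  base <- list(alcohol_per_day = 2, alcohol_per_week = 15)
  ev <- evaluate_item("alcohol", prof, do.call(measurements, base),
                      kb_default)
  expect_equal(ev$status, "off_target")  # weekly bound violated
  ev2 <- evaluate_item("alcohol", prof,
                       measurements(alcohol_per_day = 2,
                                    alcohol_per_week = 14), kb_default)
  expect_equal(ev2$status, "on_target")  # <= includes equality
  expect_true(is.na(ev2$signed_difference))

  expect_error(
    evaluate_item("exercise", prof,
                  measurements(exercise_frequency = 5,
                               exercise_duration = 70), kb_default),
    "missing measurement 'exercise_intensity'")
  for (mm in list(measurements(exercise_frequency = 4,
                               exercise_duration = 70,
                               exercise_intensity = 3),
                  measurements(exercise_frequency = 5,
                               exercise_duration = 60,
                               exercise_intensity = 3),
                  measurements(exercise_frequency = 5,
                               exercise_duration = 70,
                               exercise_intensity = "moderate"))) {
    expect_equal(evaluate_item("exercise", prof, mm, kb_default)$status,
                 "off_target")
  }
})

test_that("smoking target is strict: one cigarette a day is off-target", {
  prof <- patient_profile("female", 30, 1.65, 60)
  off <- evaluate_item("smoking", prof,
                       measurements(cigarettes_per_day = 1), kb_default)
  expect_equal(off$status, "off_target")
  on <- evaluate_item("smoking", prof,
                      measurements(cigarettes_per_day = 0), kb_default)
  expect_equal(on$status, "on_target")
  rec <- recommend_all(prof, measurements(cigarettes_per_day = 1),
                       kb_default)
  expect_equal(rec$smoking$recommendation_id, "R13")
})

test_that("recommend_all composes the three parts and maps status to kind", {
  prof <- patient_profile("female", 50, 1.60, 60)
  recs <- recommend_all(prof, measurements(waist = 92), kb_default)
  expect_length(recs, 1)
  w <- recs$waist_circumference
  expect_equal(w$recommendation_id, "R20")
  expect_equal(w$target_part, "Your target waist circumference is 88 cm")
  expect_match(w$evaluation_part, "92 cm, 4 cm over the target")
  expect_match(w$recommendation_part,
               "Reduce your waist circumference to 88 cm")
  # parts render in fixed order in the formatted text
  txt <- format(w)
  expect_true(regexpr("target waist", txt) <
              regexpr("4 cm over", txt))
  expect_true(regexpr("4 cm over", txt) <
              regexpr("Reduce your waist", txt))
  expect_equal(attr(recs, "skipped")$item,
               setdiff(vapply(kb_default$items, `[[`, character(1), "id"),
                       "waist_circumference"))
})

test_that("an all-on-target patient receives 8 maintenance/low recommendations", {
  prof <- patient_profile("female", 45, 1.60, 55)
  recs <- recommend_all(prof, all_on_target_measurements(), kb_default)
  expect_length(recs, 8)
  ids <- vapply(recs, `[[`, character(1), "recommendation_id")
  expect_setequal(unname(ids),
                  c("R1", "R5", "R7", "R9", "R12", "R14", "R17", "R19"))
  expect_equal(nrow(attr(recs, "skipped")), 0)
})

test_that("compose_recommendation enforces item and kind compatibility", {
  prof <- patient_profile("female", 50, 1.60, 60)
  ev <- evaluate_item("waist_circumference", prof, measurements(waist = 92),
                      kb_default)
  maint <- list_recommendations(kb_default, "waist_circumference")[[1]]
  expect_equal(maint$kind, "maintenance")
  expect_error(compose_recommendation(maint, ev, kb_default),
               "does not match")
  bp_tpl <- list_recommendations(kb_default, "blood_pressure")[[1]]
  expect_error(compose_recommendation(bp_tpl, ev, kb_default),
               "item")
})

test_that("fractional differences render with one decimal, integers without", {
  prof <- patient_profile("female", 50, 1.60, 60)
  ev <- evaluate_item("waist_circumference", prof,
                      measurements(waist = 88.5), kb_default)
  expect_equal(ev$evaluation_sentence,
               "Your waist circumference is 88.5 cm, 0.5 cm over the target")
  ev2 <- evaluate_item("waist_circumference", prof,
                       measurements(waist = 90), kb_default)
  expect_false(grepl("90\\.", ev2$evaluation_sentence))
})

test_that("identical inputs give byte-identical recommendation text", {
  set.seed(21)
  for (i in 1:20) {
    prof <- rand_profile()
    m <- rand_measurements()
    a <- vapply(recommend_all(prof, m, kb_default), format, character(1))
    b <- vapply(recommend_all(prof, m, kb_default), format, character(1))
    expect_identical(a, b)
  }
})

test_that("engine status agrees with a hand-coded rule oracle", {
  set.seed(22)
  items <- vapply(kb_default$items, `[[`, character(1), "id")
  for (i in 1:300) {
    prof <- rand_profile()
    m <- rand_measurements()
    for (item in items) {
      ev <- evaluate_item(item, prof, m, kb_default)
      expect_equal(ev$status, oracle_status(item, prof, m),
                   info = sprintf("item %s, case %d", item, i))
    }
  }
})

test_that("worsening a risk variable never flips off-target to on-target", {
  prof <- patient_profile("male", 55, 1.75, 78)
  worsen <- list(
    waist_circumference = function(v) measurements(waist = v),
    blood_pressure = function(v) measurements(systolic_bp = v,
                                              diastolic_bp = 50),
    smoking = function(v) measurements(cigarettes_per_day = v),
    sodium_intake = function(v) measurements(diet_behavior_score = v),
    stress = function(v) measurements(bepsik_score = v)
  )
  grids <- list(waist_circumference = seq(70, 130, by = 2.5),
                blood_pressure = seq(100, 200, by = 5),
                smoking = 0:20,
                sodium_intake = 0:12,
                stress = seq(1, 5, by = 0.2))
  for (item in names(worsen)) {
    st <- vapply(grids[[item]], function(v)
      evaluate_item(item, prof, worsen[[item]](v), kb_default)$status,
      character(1))
    off <- st == "off_target"
    # once off-target, stays off-target as the variable worsens
    expect_true(all(diff(off) >= 0), info = item)
  }
})
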