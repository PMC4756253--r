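#' Patient profile
#'
#' The demographic and clinical facts that drive target setting: sex, age,
#' height, weight, and the comorbidity flags whose disjunction forms the
#' "underlying disease" condition of the blood-pressure rule (diabetes
#' mellitus and/or chronic renal disease). Guideline scope is adults, so
#' age must be at least 18.
#'
#' @param sex `"male"` or `"female"`.
#' @param age Age in whole years (>= 18).
#' @param height Height in metres.
#' @param weight Weight in kg.
#' @param has_diabetes,has_chronic_renal_disease Comorbidity flags.
#' @return An object of class `hma_profile`.
#' @examples
#' patient_profile("female", 45, 1.60, 55)
#' @export
patient_profile <- function(sex, age, height, weight,
                            has_diabetes = FALSE,
                            has_chronic_renal_disease = FALSE) {
  sex <- match.arg(sex, c("male", "female"))
  if (!is_scalar_number(age) || age < 18)
    stopf("age must be a number >= 18 (guideline scope is adults), got %s",
          format(age))
  if (!is_scalar_number(height) || height <= 0)
    stopf("height must be a positive number of metres")
  if (height > 3)
    stopf("height is in metres; %s looks like centimetres", format(height))
  if (!is_scalar_number(weight) || weight <= 0)
    stopf("weight must be a positive number of kg")
  stopifnot(is.logical(has_diabetes), is.logical(has_chronic_renal_disease))
  structure(list(
    sex = sex,
    age = as.integer(age),
    height = as.numeric(height),
    weight = as.numeric(weight),
    has_diabetes = has_diabetes,
    has_chronic_renal_disease = has_chronic_renal_disease,
    underlying_disease = isTRUE(has_diabetes) || isTRUE(has_chronic_renal_disease)
  ), class = "hma_profile")
}

#' @export
print.hma_profile <- function(x, ...) {
  cat(sprintf("<hma_profile> %s, %d y, %.2f m, %.1f kg, underlying disease: %s\n",
              x$sex, x$age, x$height, x$weight,
              if (x$underlying_disease) "yes" else "no"))
  invisible(x)
}

#' Patient measurements
#'
#' One round of self-reported measurements for the rules engine. Every
#' field is optional (`NA`); items whose measurements are missing are
#' reported as unevaluable rather than guessed at. Diastolic blood
#' pressure is recorded but never ruled on: the guideline targets are
#' systolic only.
#'
#' @param systolic_bp,diastolic_bp Blood pressure in mmHg.
#' @param waist Waist circumference in cm.
#' @param weight Current body weight in kg.
#' @param diet_behavior_score Total of the 12-item diet-behavior
#'   questionnaire (0-12), see [score_diet_behavior()].
#' @param bepsik_score Mean BEPSI-K stress score (1-5), see
#'   [score_bepsik()].
#' @param alcohol_per_day,alcohol_per_week Glasses of alcohol.
#' @param cigarettes_per_day Cigarettes smoked per day.
#' @param exercise_frequency Exercise sessions per week.
#' @param exercise_duration Minutes per session.
#' @param exercise_intensity `"light"`, `"moderate"`, `"vigorous"`, or the
#'   ordinal codes 1-3.
#' @return An object of class `hma_measurements`.
#' @examples
#' measurements(systolic_bp = 128, waist = 92)
#' @export
measurements <- function(systolic_bp = NA, diastolic_bp = NA, waist = NA,
                         weight = NA, diet_behavior_score = NA,
                         bepsik_score = NA, alcohol_per_day = NA,
                         alcohol_per_week = NA, cigarettes_per_day = NA,
                         exercise_frequency = NA, exercise_duration = NA,
                         exercise_intensity = NA) {
  chk <- function(x, name, lo = 0, hi = Inf, integer = FALSE) {
    if (length(x) != 1L) stopf("%s must be a single value", name)
    if (is.na(x)) return(NA_real_)
    x <- as.numeric(x)
    if (!is.finite(x) || x < lo || x > hi)
      stopf("%s out of range [%s, %s]: %s", name, lo, hi, format(x))
    if (integer && abs(x - round(x)) > 1e-9)
      stopf("%s must be an integer, got %s", name, format(x))
    x
  }
  if (length(exercise_intensity) == 1L && is.character(exercise_intensity)) {
    exercise_intensity <- match(
      match.arg(exercise_intensity, c("light", "moderate", "vigorous")),
      c("light", "moderate", "vigorous"))
  }
  m <- list(
    systolic_bp = chk(systolic_bp, "systolic_bp", 50, 300),
    diastolic_bp = chk(diastolic_bp, "diastolic_bp", 20, 200),
    waist = chk(waist, "waist", 30, 250),
    weight = chk(weight, "weight", 20, 400),
    diet_behavior_score = chk(diet_behavior_score, "diet_behavior_score",
                              0, 12, integer = TRUE),
    bepsik_score = chk(bepsik_score, "bepsik_score", 1, 5),
    alcohol_per_day = chk(alcohol_per_day, "alcohol_per_day"),
    alcohol_per_week = chk(alcohol_per_week, "alcohol_per_week"),
    cigarettes_per_day = chk(cigarettes_per_day, "cigarettes_per_day",
                             integer = TRUE),
    exercise_frequency = chk(exercise_frequency, "exercise_frequency",
                             0, 7 * 10),
    exercise_duration = chk(exercise_duration, "exercise_duration"),
    exercise_intensity = chk(exercise_intensity, "exercise_intensity", 1, 3,
                             integer = TRUE)
  )
  if (!is.na(m$systolic_bp) && !is.na(m$diastolic_bp) &&
      m$systolic_bp <= m$diastolic_bp)
    stopf("systolic_bp must exceed diastolic_bp")
  structure(m, class = "hma_measurements")
}

#' @export
print.hma_measurements <- function(x, ...) {
  present <- Filter(function(v) !is.na(v), unclass(x))
  cat("<hma_measurements>", length(present), "of", length(x),
      "fields present\n")
  for (nm in names(present)) cat(" ", nm, "=", present[[nm]], "\n")
  invisible(x)
}

intensity_label <- function(code) c("light", "moderate", "vigorous")[code]
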