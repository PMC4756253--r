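# Rules engine: per-patient target setting and composition of three-part
# tailored recommendations (target sentence, evaluation result,
# recommendation), driven entirely by the knowledge base.

profile_facts <- function(profile) {
  stopifnot(inherits(profile, "hma_profile"))
  unclass(profile)
}

cond_holds <- function(when, facts, rule_id) {
  if (identical(when, "always") || identical(when, "else")) return(TRUE)
  for (cl in when$all) {
    val <- facts[[cl$field]]
    if (is.null(val) || (length(val) == 1L && is.na(val)))
      stopf("rule %s needs profile field '%s', which is missing",
            rule_id, cl$field)
    if (!isTRUE(apply_op(val, cl$op, cl$value))) return(FALSE)
  }
  TRUE
}

fire_branch <- function(group, facts) {
  for (b in group$branches) {
    if (cond_holds(b$when, facts, b$rule_id)) return(b)
  }
  stopf("no branch of rule group '%s' fired; knowledge base is not exhaustive",
        group$group)
}

resolve_criteria <- function(branch, facts) {
  lapply(branch$criteria, function(cr) {
    thr <- if (!is.null(cr$threshold)) as.numeric(cr$threshold)
           else eval_formula(cr$formula, facts)
    list(measure = cr$measure, comparator = cr$comparator,
         threshold = thr, unit = cr$unit)
  })
}

# suffix used to name placeholders when an item has several criteria
measure_suffix <- c(alcohol_per_day = "day", alcohol_per_week = "week",
                    exercise_frequency = "frequency",
                    exercise_duration = "duration",
                    exercise_intensity = "intensity")

target_placeholders <- function(criteria) {
  data <- list()
  if (length(criteria) == 1L) {
    data$target <- fmt_num(criteria[[1]]$threshold)
  } else {
    for (cr in criteria) {
      sfx <- measure_suffix[[cr$measure]]
      data[[paste0("target_", sfx)]] <- fmt_num(cr$threshold)
    }
  }
  data
}

measured_placeholders <- function(criteria, values) {
  data <- list()
  if (length(criteria) == 1L) {
    data$measured <- fmt_num(values[[1]])
  } else {
    for (i in seq_along(criteria)) {
      sfx <- measure_suffix[[criteria[[i]]$measure]]
      val <- if (identical(criteria[[i]]$measure, "exercise_intensity"))
        intensity_label(values[[i]]) else fmt_num(values[[i]])
      data[[paste0("measured_", sfx)]] <- val
    }
  }
  data
}

#' Set per-patient targets for all intervention items
#'
#' Applies the 8 target-setting rule groups of the knowledge base to a
#' patient profile and returns fully resolved targets: the systolic
#' blood-pressure branch (below 150 mmHg for patients aged 60 or over with
#' neither diabetes nor chronic renal disease, below 140 mmHg otherwise),
#' the body-weight bound of 25 x height^2 (a BMI of 25 kg/m2), the
#' sex-and-weight alcohol branch, the sex-specific waist bound, and the
#' fixed diet, smoking, stress and exercise targets.
#'
#' @param profile A [patient_profile()].
#' @param kb A knowledge base from [load_default_kb()].
#' @return An object of class `hma_target_set`: a named list (one entry
#'   per item) of resolved targets, each with `item`, `rule_id`,
#'   `target_sentence_id`, `criteria` (measure, comparator, numeric
#'   threshold, unit) and the rendered `target_sentence`.
#' @examples
#' kb <- load_default_kb()
#' ts <- set_targets(patient_profile("female", 45, 1.6, 55), kb)
#' ts$entries$waist_circumference$criteria[[1]]$threshold  # 88
#' @export
set_targets <- function(profile, kb) {
  stopifnot(inherits(kb, "hma_kb"))
  facts <- profile_facts(profile)
  entries <- list()
  for (g in kb$target_rules) {
    b <- fire_branch(g, facts)
    criteria <- resolve_criteria(b, facts)
    data <- target_placeholders(criteria)
    entries[[g$item]] <- list(
      item = g$item,
      rule_id = b$rule_id,
      target_sentence_id = b$target_sentence_id,
      criteria = criteria,
      target_sentence = render_template(
        kb$sentences$targets[[b$target_sentence_id]], data)
    )
  }
  structure(list(entries = entries, profile = profile),
            class = "hma_target_set")
}

#' @export
print.hma_target_set <- function(x, ...) {
  cat("<hma_target_set>\n")
  for (e in x$entries) {
    cat(sprintf("  %-20s [%s] %s\n", e$item, e$target_sentence_id,
                e$target_sentence))
  }
  invisible(x)
}

find_eval_rule <- function(kb, item, branch, target_rule_id) {
  for (er in kb$evaluation_rules) {
    if (identical(er$item, item) && identical(er$branch, branch) &&
        (identical(er$target_branch, "any") ||
         identical(er$target_branch, target_rule_id)))
      return(er)
  }
  stopf("no evaluation rule for item '%s', branch '%s'", item, branch)
}

#' Evaluate one intervention item against its target
#'
#' Compares the relevant measurement(s) with the patient's resolved target
#' for one item and selects the matching evaluation rule. Items with a
#' single scalar criterion report the signed difference (measured minus
#' target threshold); the conjunction items (alcohol, exercise) do not.
#' Stress is classified into low/moderate/high via
#' [classify_stress_level()] using the knowledge-base cutpoints.
#'
#' @param item A target item id, e.g. `"waist_circumference"`.
#' @param profile A [patient_profile()].
#' @param m A [measurements()] record.
#' @param kb A knowledge base.
#' @return An object of class `hma_evaluation` with `status`
#'   (`"on_target"`/`"off_target"`), `level` (stress only), `measured`,
#'   `target`, `signed_difference`, the rendered `evaluation_sentence`
#'   and the ids of the rules that fired.
#' @examples
#' kb <- load_default_kb()
#' ev <- evaluate_item("waist_circumference",
#'                     patient_profile("female", 50, 1.6, 60),
#'                     measurements(waist = 92), kb)
#' ev$status            # "off_target"
#' ev$signed_difference # 4
#' @export
evaluate_item <- function(item, profile, m, kb) {
  stopifnot(inherits(kb, "hma_kb"), inherits(m, "hma_measurements"))
  if (!item %in% kb_item_ids(kb)) stopf("unknown target item id: %s", item)
  facts <- profile_facts(profile)
  g <- kb_group(kb, item)
  b <- fire_branch(g, facts)
  criteria <- resolve_criteria(b, facts)

  values <- lapply(criteria, function(cr) {
    val <- m[[cr$measure]]
    if (is.null(val) || is.na(val))
      stopf("missing measurement '%s' needed to evaluate item '%s'",
            cr$measure, item)
    val
  })

  ok <- mapply(function(cr, v) isTRUE(apply_op(v, cr$comparator, cr$threshold)),
               criteria, values)
  status <- if (all(ok)) "on_target" else "off_target"

  level <- NA_character_
  if (identical(item, "stress")) {
    level <- classify_stress_level(values[[1]],
                                   cutpoints = kb$config$stress_cutpoints)
    branch_label <- level
  } else {
    branch_label <- if (identical(status, "on_target")) "maintain" else "modify"
  }

  signed_difference <- if (length(criteria) == 1L)
    values[[1]] - criteria[[1]]$threshold else NA_real_

  er <- find_eval_rule(kb, item, branch_label, b$rule_id)

  data <- c(target_placeholders(criteria),
            measured_placeholders(criteria, values))
  if (length(criteria) == 1L) {
    data$diff <- fmt_num(abs(signed_difference))
    data$direction <- if (signed_difference >= 0) "over" else "under"
  }
  if (!is.na(level)) data$level <- level

  structure(list(
    item = item,
    status = status,
    level = level,
    branch = branch_label,
    measured = stats::setNames(values,
                               vapply(criteria, `[[`, character(1), "measure")),
    target = stats::setNames(lapply(criteria, `[[`, "threshold"),
                             vapply(criteria, `[[`, character(1), "measure")),
    signed_difference = signed_difference,
    target_rule_id = b$rule_id,
    target_sentence_id = b$target_sentence_id,
    target_sentence = render_template(
      kb$sentences$targets[[b$target_sentence_id]], data),
    evaluation_rule_id = er$rule_id,
    evaluation_sentence_id = er$evaluation_sentence_id,
    evaluation_sentence = render_template(
      kb$sentences$evaluations[[er$evaluation_sentence_id]], data),
    recommendation_id = er$recommendation_id,
    placeholders = data
  ), class = "hma_evaluation")
}

#' @export
print.hma_evaluation <- function(x, ...) {
  cat(sprintf("<hma_evaluation> %s: %s (%s -> %s)\n", x$item,
              if (is.na(x$level)) x$status else paste0("stress ", x$level),
              x$evaluation_sentence_id, x$recommendation_id))
  cat(" ", x$evaluation_sentence, "\n")
  invisible(x)
}

template_kind_matches <- function(kind, evaluation) {
  if (!is.na(evaluation$level))
    return(identical(kind, paste0("stress_", evaluation$level)))
  switch(kind,
    maintenance = identical(evaluation$status, "on_target"),
    modification = identical(evaluation$status, "off_target"),
    FALSE)
}

#' Compose a three-part tailored recommendation
#'
#' Fills a recommendation template with the resolved target and measured
#' values of an evaluation, producing the fixed three-part structure:
#' target sentence, evaluation-result sentence, recommendation sentence
#' (plus any optional detail recommendations). Identical inputs always
#' yield identical text.
#'
#' @param template A template from [list_recommendations()].
#' @param evaluation An [evaluate_item()] result for the same item and a
#'   matching status/level.
#' @param kb The knowledge base the two came from.
#' @return An object of class `hma_recommendation` with `target_part`,
#'   `evaluation_part`, `recommendation_part`, `recommendation_id` and
#'   `detail_options`.
#' @export
compose_recommendation <- function(template, evaluation, kb) {
  stopifnot(inherits(evaluation, "hma_evaluation"))
  if (!identical(template$item, evaluation$item))
    stopf("template is for item '%s' but evaluation is for '%s'",
          template$item, evaluation$item)
  if (!template_kind_matches(template$kind, evaluation))
    stopf("template kind '%s' does not match evaluation status '%s'",
          template$kind,
          if (is.na(evaluation$level)) evaluation$status else evaluation$level)
  structure(list(
    item = evaluation$item,
    target_part = evaluation$target_sentence,
    evaluation_part = evaluation$evaluation_sentence,
    recommendation_part = render_template(template$recommendation_sentence,
                                          evaluation$placeholders),
    recommendation_id = template$recommendation_id,
    detail_options = unlist(template$detail_options) %||% character(0)
  ), class = "hma_recommendation")
}

#' @export
format.hma_recommendation <- function(x, ...) {
  parts <- c(x$target_part, x$evaluation_part, x$recommendation_part)
  txt <- paste0(paste(parts, collapse = ". "), ".")
  if (length(x$detail_options) > 0) {
    txt <- paste0(txt, "\n", paste0("  - ", x$detail_options, collapse = "\n"))
  }
  txt
}

#' @export
print.hma_recommendation <- function(x, ...) {
  cat(sprintf("[%s] %s\n", x$recommendation_id, format(x)))
  invisible(x)
}

#' Produce tailored recommendations for all evaluable items
#'
#' Evaluates every intervention item for which the needed measurements are
#' present and composes one base recommendation per item: the maintenance
#' template when the item is on target, the modification template when it
#' is not, and the stress-level template for stress. Items with missing
#' measurements are skipped and reported in the `skipped` attribute.
#'
#' @inheritParams evaluate_item
#' @return An object of class `hma_recommendation_set`: a named list of
#'   `hma_recommendation` (at most 8), with attribute `skipped`, a data
#'   frame naming each skipped item and its missing measurement.
#' @examples
#' kb <- load_default_kb()
#' recs <- recommend_all(patient_profile("female", 50, 1.6, 60),
#'                       measurements(waist = 92), kb)
#' recs$waist_circumference$recommendation_id  # "R20"
#' @export
recommend_all <- function(profile, m, kb) {
  stopifnot(inherits(kb, "hma_kb"))
  recs <- list()
  skipped <- list()
  for (item in kb_item_ids(kb)) {
    ev <- tryCatch(evaluate_item(item, profile, m, kb),
                   error = function(e) e)
    if (inherits(ev, "error")) {
      if (grepl("missing measurement", conditionMessage(ev))) {
        skipped[[length(skipped) + 1L]] <-
          data.frame(item = item, reason = conditionMessage(ev),
                     stringsAsFactors = FALSE)
        next
      }
      stop(ev)
    }
    template <- kb_template(kb, ev$recommendation_id)
    recs[[item]] <- compose_recommendation(template, ev, kb)
  }
  skipped <- if (length(skipped) > 0) do.call(rbind, skipped) else
    data.frame(item = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  structure(recs, skipped = skipped, class = "hma_recommendation_set")
}

#' @export
print.hma_recommendation_set <- function(x, ...) {
  cat("<hma_recommendation_set>", length(x), "recommendation(s)\n")
  for (r in x) cat("\n", format(r), "\n", sep = "")
  sk <- attr(x, "skipped")
  if (nrow(sk) > 0) {
    cat("\nskipped (missing measurements):",
        paste(sk$item, collapse = ", "), "\n")
  }
  invisible(x)
}
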