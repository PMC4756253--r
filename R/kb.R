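#' Load a hypertension-management knowledge base
#'
#' The knowledge base holds the guideline-derived rules as data: 8
#' target-setting rule groups (one per intervention item), 20 evaluation
#' rules, 17 base three-part recommendation templates, the target and
#' evaluation sentence templates they reference, and the data dictionary of
#' engine inputs and outputs. `load_default_kb()` reads the knowledge file
#' bundled with the package; `load_kb()` reads any file with the same
#' schema (YAML).
#'
#' Loading performs structural schema checks (required sections and fields)
#' and fails with the name of the offending entry if they are violated.
#' Semantic invariants (cardinalities, referential integrity,
#' exhaustiveness) are reported by [validate_kb()], which returns a report
#' rather than raising, so that deliberately broken knowledge bases can be
#' inspected.
#'
#' @param path Path to a knowledge-base YAML file.
#' @return An object of class `hma_kb`: a list with elements `items`,
#'   `target_rules`, `evaluation_rules`, `recommendation_templates`,
#'   `sentences`, `data_dictionary`, `config`, `version`, `locale`.
#' @examples
#' kb <- load_default_kb()
#' length(kb$target_rules)            # 8 rule groups
#' length(kb$evaluation_rules)        # 20 evaluation rules
#' length(kb$recommendation_templates) # 17 base templates
#' @export
load_kb <- function(path) {
  if (!file.exists(path)) stopf("knowledge base file not found: %s", path)
  raw <- yaml::read_yaml(path)

  required <- c("version", "items", "target_rules", "evaluation_rules",
                "recommendation_templates", "sentences", "data_dictionary")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stopf("knowledge base is missing section(s): %s",
          paste(missing, collapse = ", "))
  }

  check_fields <- function(entries, fields, what, key) {
    for (e in entries) {
      miss <- setdiff(fields, names(e))
      if (length(miss) > 0) {
        stopf("%s entry '%s' is missing field(s): %s",
              what, e[[key]] %||% "<unnamed>", paste(miss, collapse = ", "))
      }
    }
  }
  check_fields(raw$items, c("id", "label", "unit"), "item", "id")
  check_fields(raw$target_rules, c("group", "item", "branches"),
               "target rule group", "group")
  for (g in raw$target_rules) {
    check_fields(g$branches,
                 c("rule_id", "target_sentence_id", "when", "criteria"),
                 "target rule branch", "rule_id")
    for (b in g$branches) {
      for (cr in b$criteria) {
        if (is.null(cr$measure) || is.null(cr$comparator) ||
            (is.null(cr$threshold) && is.null(cr$formula))) {
          stopf("criterion of branch '%s' needs measure, comparator and a threshold or formula",
                b$rule_id)
        }
      }
    }
  }
  check_fields(raw$evaluation_rules,
               c("rule_id", "item", "target_branch", "branch",
                 "evaluation_sentence_id", "recommendation_id"),
               "evaluation rule", "rule_id")
  check_fields(raw$recommendation_templates,
               c("recommendation_id", "item", "kind",
                 "recommendation_sentence"),
               "recommendation template", "recommendation_id")
  check_fields(raw$data_dictionary,
               c("name", "group", "value_type", "unit",
                 "nursing_process_category"),
               "data dictionary", "name")

  kb <- raw
  kb$config <- kb$config %||% list()
  kb$config$stress_cutpoints <- kb$config$stress_cutpoints %||%
    list(low_max = 1.6, moderate_max = 2.8)
  kb$config$mms_factors <- kb$config$mms_factors %||%
    list(motivation = c(1, 2, 6), knowledge = c(3, 4, 5))
  class(kb) <- "hma_kb"
  kb
}

#' @rdname load_kb
#' @export
load_default_kb <- function() {
  load_kb(system.file("extdata", "hma_kb.yaml", package = "hmaguide",
                      mustWork = TRUE))
}

#' @export
print.hma_kb <- function(x, ...) {
  cat("<hma_kb> version", x$version, "\n")
  cat("  items:                   ", length(x$items), "\n")
  cat("  target rule groups:      ", length(x$target_rules), "\n")
  cat("  evaluation rules:        ", length(x$evaluation_rules), "\n")
  cat("  recommendation templates:", length(x$recommendation_templates), "\n")
  cat("  data dictionary entries: ", length(x$data_dictionary), "\n")
  invisible(x)
}

kb_item_ids <- function(kb) vapply(kb$items, `[[`, character(1), "id")

kb_item <- function(kb, id) {
  for (it in kb$items) if (identical(it$id, id)) return(it)
  stopf("unknown target item id: %s", id)
}

kb_group <- function(kb, item) {
  for (g in kb$target_rules) if (identical(g$item, item)) return(g)
  stopf("no target rule group for item: %s", item)
}

kb_template <- function(kb, recommendation_id) {
  for (tp in kb$recommendation_templates) {
    if (identical(tp$recommendation_id, recommendation_id)) return(tp)
  }
  stopf("no recommendation template with id: %s", recommendation_id)
}

#' List recommendation templates
#'
#' Returns the base recommendation templates of a knowledge base, optionally
#' filtered to one intervention item, in stable order of appearance
#' (recommendation id order in the default knowledge base).
#'
#' @param kb A knowledge base from [load_kb()].
#' @param item Optional target item id (e.g. `"waist_circumference"`).
#' @return A list of template entries, each with `recommendation_id`,
#'   `item`, `kind`, `recommendation_sentence` and `detail_options`.
#' @examples
#' kb <- load_default_kb()
#' length(list_recommendations(kb))            # 17
#' length(list_recommendations(kb, "stress"))  # 3
#' @export
list_recommendations <- function(kb, item = NULL) {
  stopifnot(inherits(kb, "hma_kb"))
  out <- kb$recommendation_templates
  if (!is.null(item)) {
    if (!item %in% kb_item_ids(kb)) stopf("unknown target item id: %s", item)
    out <- Filter(function(tp) identical(tp$item, item), out)
  }
  out
}

#' Validate a knowledge base against its invariants
#'
#' Checks the semantic invariants of the knowledge base and reports every
#' violation found: cardinalities (8 target rule groups, 20 evaluation
#' rules, 17 base templates of which 3 stress-level), uniqueness of ids,
#' referential integrity between evaluation rules, sentences and templates,
#' exhaustive rule groups (a final catch-all branch), and data-dictionary
#' coverage of every field a rule consumes. Violations are report rows, not
#' errors.
#'
#' @param kb A knowledge base from [load_kb()].
#' @return A data frame of class `hma_kb_validation` with columns `check`,
#'   `where`, `message`; zero rows for a valid knowledge base.
#' @examples
#' rep <- validate_kb(load_default_kb())
#' nrow(rep)  # 0
#' @export
validate_kb <- function(kb) {
  v <- list()
  add <- function(check, where, message) {
    v[[length(v) + 1L]] <<- data.frame(check = check, where = where,
                                       message = message,
                                       stringsAsFactors = FALSE)
  }

  item_ids <- kb_item_ids(kb)
  if (length(kb$items) != 8L)
    add("count", "items", sprintf("expected 8 target items, found %d",
                                  length(kb$items)))
  if (anyDuplicated(item_ids))
    add("unique", "items", "duplicate target item ids")

  ## target rules: 8 groups, one per item, exhaustive
  if (length(kb$target_rules) != 8L)
    add("count", "target_rules",
        sprintf("expected 8 target rule groups, found %d",
                length(kb$target_rules)))
  groups <- vapply(kb$target_rules, `[[`, character(1), "item")
  if (anyDuplicated(groups))
    add("unique", "target_rules", "more than one rule group for an item")
  for (miss in setdiff(item_ids, groups))
    add("coverage", miss, "item has no target rule group")
  branch_ids <- character(0)
  for (g in kb$target_rules) {
    if (!g$item %in% item_ids)
      add("reference", g$group, "rule group for unknown item")
    n <- length(g$branches)
    last_when <- g$branches[[n]]$when
    if (!identical(last_when, "else") && !identical(last_when, "always"))
      add("exhaustive", g$group,
          "final branch is conditional; group may not fire for some profiles")
    branch_ids <- c(branch_ids,
                    vapply(g$branches, `[[`, character(1), "rule_id"))
    for (b in g$branches) {
      if (!b$target_sentence_id %in% names(kb$sentences$targets))
        add("reference", b$rule_id,
            sprintf("dangling target sentence id %s", b$target_sentence_id))
    }
  }
  if (anyDuplicated(branch_ids))
    add("unique", "target_rules", "duplicate branch rule_id")

  ## evaluation rules: 20, references resolve
  if (length(kb$evaluation_rules) != 20L)
    add("count", "evaluation_rules",
        sprintf("expected 20 evaluation rules, found %d",
                length(kb$evaluation_rules)))
  template_ids <- vapply(kb$recommendation_templates, `[[`, character(1),
                         "recommendation_id")
  for (er in kb$evaluation_rules) {
    if (!er$item %in% item_ids)
      add("reference", er$rule_id, "evaluation rule for unknown item")
    if (!er$recommendation_id %in% template_ids)
      add("reference", er$rule_id,
          sprintf("dangling recommendation id %s", er$recommendation_id))
    if (!er$evaluation_sentence_id %in% names(kb$sentences$evaluations))
      add("reference", er$rule_id,
          sprintf("dangling evaluation sentence id %s",
                  er$evaluation_sentence_id))
    if (!identical(er$target_branch, "any") &&
        !er$target_branch %in% branch_ids)
      add("reference", er$rule_id,
          sprintf("dangling target branch %s", er$target_branch))
  }

  ## templates: 17 base, 3 stress, one maintenance + one modification per
  ## non-stress item
  if (length(kb$recommendation_templates) != 17L)
    add("count", "recommendation_templates",
        sprintf("expected 17 base templates, found %d",
                length(kb$recommendation_templates)))
  if (anyDuplicated(template_ids))
    add("unique", "recommendation_templates", "duplicate recommendation ids")
  kinds <- vapply(kb$recommendation_templates, `[[`, character(1), "kind")
  stress_kinds <- c("stress_low", "stress_moderate", "stress_high")
  if (sum(kinds %in% stress_kinds) != 3L)
    add("count", "recommendation_templates",
        "expected exactly 3 stress-level templates")
  for (id in setdiff(item_ids, "stress")) {
    tpl <- Filter(function(tp) identical(tp$item, id),
                  kb$recommendation_templates)
    k <- sort(vapply(tpl, `[[`, character(1), "kind"))
    if (!identical(k, c("maintenance", "modification")))
      add("count", id,
          "expected one maintenance and one modification template")
  }

  ## every evaluation branch of every item has a rule; each non-stress item
  ## needs both maintain and modify rules, stress all three levels
  for (id in item_ids) {
    br <- vapply(Filter(function(er) identical(er$item, id),
                        kb$evaluation_rules),
                 `[[`, character(1), "branch")
    need <- if (identical(id, "stress")) c("low", "moderate", "high")
            else c("maintain", "modify")
    for (m in setdiff(need, br))
      add("coverage", id, sprintf("no evaluation rule for branch '%s'", m))
  }

  ## data dictionary: unique names, covers rule inputs
  dict_names <- vapply(kb$data_dictionary, `[[`, character(1), "name")
  if (anyDuplicated(dict_names))
    add("unique", "data_dictionary", "duplicate dictionary names")
  used <- character(0)
  for (g in kb$target_rules) for (b in g$branches) {
    if (is.list(b$when)) {
      used <- c(used, vapply(b$when$all, `[[`, character(1), "field"))
    }
    for (cr in b$criteria) {
      used <- c(used, cr$measure)
      if (!is.null(cr$formula)) {
        used <- c(used, setdiff(all.names(str2lang(cr$formula), unique = TRUE),
                                c("+", "-", "*", "/", "^", "(")))
      }
    }
  }
  for (f in setdiff(unique(used), dict_names))
    add("coverage", f, "field used by a rule but absent from the data dictionary")

  out <- if (length(v) == 0) {
    data.frame(check = character(0), where = character(0),
               message = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, v)
  }
  class(out) <- c("hma_kb_validation", class(out))
  out
}

#' @export
print.hma_kb_validation <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("knowledge base OK: 0 violations\n")
  } else {
    cat(nrow(x), "violation(s):\n")
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}
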