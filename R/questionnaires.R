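# Scoring of the three patient instruments (Modified Morisky Scale,
# 12-item diet-behavior questionnaire, BEPSI-K) and of the deployment
# survey instruments (perceived usefulness, user satisfaction).

check_binary_vector <- function(items, n, name) {
  if (length(items) != n)
    stopf("%s needs exactly %d items, got %d", name, n, length(items))
  if (any(is.na(items)) || !all(items %in% c(0, 1)))
    stopf("%s items must all be 0 or 1", name)
  as.integer(items)
}

#' Score the Modified Morisky Scale (MMS)
#'
#' The MMS is a 6-item yes/no medication-adherence instrument. Each item
#' is coded 1 (adherent) or 0 (non-adherent) after reverse-keying at
#' ingestion (see [mms_recode()]); the total score is the item sum (0-6).
#' The scale has two factors, a motivation subscale and a knowledge
#' subscale, whose item partition is configurable (the default places
#' items 1, 2 and 6 in motivation and 3, 4, 5 in knowledge, and can be
#' overridden from the knowledge-base `config$mms_factors`).
#'
#' @param items Vector of 6 values in \{0, 1\}, adherent-coded.
#' @param factors Named list with integer vectors `motivation` and
#'   `knowledge` partitioning 1:6.
#' @return An object of class `hma_mms_score` with `total`, `motivation`
#'   and `knowledge` (total = motivation + knowledge).
#' @examples
#' score_mms(c(1, 1, 0, 1, 0, 1))$total  # 4
#' @export
score_mms <- function(items,
                      factors = list(motivation = c(1, 2, 6),
                                     knowledge = c(3, 4, 5))) {
  items <- check_binary_vector(items, 6L, "MMS")
  part <- sort(c(factors$motivation, factors$knowledge))
  if (!identical(as.integer(part), 1:6))
    stopf("factor partition must split items 1..6 into two disjoint sets")
  structure(list(
    total = sum(items),
    motivation = sum(items[factors$motivation]),
    knowledge = sum(items[factors$knowledge])
  ), class = "hma_mms_score")
}

#' @export
print.hma_mms_score <- function(x, ...) {
  cat(sprintf("MMS %d/6 (motivation %d, knowledge %d)\n",
              x$total, x$motivation, x$knowledge))
  invisible(x)
}

#' Recode raw MMS yes/no answers to adherent-coded 0/1
#'
#' Raw Morisky-style questions are phrased so that for most items the
#' adherent answer is "no" (e.g. "Do you ever forget to take your
#' medicine?"). This helper performs the reverse-keying once, at
#' ingestion; the engine and scorer only ever see adherent-coded 0/1.
#'
#' @param answers Character vector of 6 `"yes"`/`"no"` answers.
#' @param adherent_is_no Logical vector of length 6; `TRUE` where "no" is
#'   the adherent answer (the default for every item).
#' @return Integer vector of 6 values in \{0, 1\}, adherent = 1.
#' @export
mms_recode <- function(answers, adherent_is_no = rep(TRUE, 6)) {
  if (length(answers) != 6L) stopf("expected 6 answers, got %d", length(answers))
  answers <- tolower(trimws(answers))
  if (!all(answers %in% c("yes", "no"))) stopf("answers must be yes/no")
  yes <- answers == "yes"
  as.integer(ifelse(adherent_is_no, !yes, yes))
}

#' Score the 12-item diet-behavior questionnaire
#'
#' Binary sodium-related behaviors (1 = high-sodium behavior); the total
#' (0-12) is used by the rules engine as a proxy classifier for high vs
#' low sodium intake (on-target below 5).
#'
#' @param items Vector of 12 values in \{0, 1\}.
#' @return Integer total in 0..12.
#' @examples
#' score_diet_behavior(rep(c(1, 0), 6))  # 6
#' @export
score_diet_behavior <- function(items) {
  sum(check_binary_vector(items, 12L, "diet-behavior"))
}

#' Score the BEPSI-K stress instrument
#'
#' The Korean Brief Encounter Psychosocial Instrument has 5 Likert items
#' scored 1-5; the scale score is the arithmetic item mean, so it lies in
#' \[1, 5\]. The guideline on-target bound used by the rules engine is a
#' score of at most 1.6.
#'
#' @param items Vector of 5 integers in 1..5.
#' @return Mean score (numeric, in \[1, 5\]).
#' @examples
#' score_bepsik(c(2, 2, 1, 2, 1))  # 1.6
#' @export
score_bepsik <- function(items) {
  if (length(items) != 5L)
    stopf("BEPSI-K needs exactly 5 items, got %d", length(items))
  if (any(is.na(items)) || !all(items %in% 1:5))
    stopf("BEPSI-K items must be integers in 1..5")
  mean(items)
}

#' Classify a BEPSI-K score into a stress level
#'
#' Three levels drive the three stress recommendation templates. The low
#' bound (1.6) is the guideline on-target bound; the moderate/high
#' cutpoint (default 2.8) is configurable via the knowledge base.
#'
#' @param score BEPSI-K mean score in \[1, 5\].
#' @param cutpoints List or named vector with `low_max` and `moderate_max`
#'   (strictly increasing).
#' @return `"low"`, `"moderate"` or `"high"`.
#' @examples
#' classify_stress_level(1.6)  # "low"
#' @export
classify_stress_level <- function(score,
                                  cutpoints = list(low_max = 1.6,
                                                   moderate_max = 2.8)) {
  if (!is_scalar_number(score) || score < 1 || score > 5)
    stopf("BEPSI-K score must lie in [1, 5], got %s", format(score))
  lo <- as.numeric(cutpoints$low_max %||% cutpoints["low_max"])
  mid <- as.numeric(cutpoints$moderate_max %||% cutpoints["moderate_max"])
  if (!(lo < mid)) stopf("stress cutpoints must be strictly increasing")
  if (score <= lo) "low" else if (score <= mid) "moderate" else "high"
}

check_likert_matrix <- function(responses, n_items, name) {
  m <- as.matrix(as.data.frame(responses))
  if (ncol(m) == 1L && n_items > 1L) m <- t(m)
  if (ncol(m) != n_items)
    stopf("%s needs %d items per respondent, got %d", name, n_items, ncol(m))
  if (nrow(m) == 0L) stopf("%s: empty response collection", name)
  if (any(is.na(m)) || any(m < 1) || any(m > 5))
    stopf("%s items must lie in [1, 5]", name)
  m
}

#' Summarize perceived-usefulness survey responses
#'
#' Six 5-point Likert items per respondent; the reported score is the mean
#' of the six item means, rounded to one decimal (per-item means are
#' reported the same way). Summaries are invariant under respondent
#' reordering.
#'
#' @param responses A matrix or data frame, one row per respondent, six
#'   columns of values in \[1, 5\].
#' @return List with `item_means` (rounded to 1 decimal), `overall`
#'   (mean of item means, 1 decimal), `n`, and the unrounded
#'   `item_means_raw`/`overall_raw`.
#' @examples
#' summarize_usefulness(rbind(rep(3, 6), rep(4, 6)))$overall  # 3.5
#' @export
summarize_usefulness <- function(responses) {
  m <- check_likert_matrix(responses, 6L, "usefulness survey")
  item_means <- colMeans(m)
  overall <- mean(item_means)
  list(item_means = round(item_means, 1),
       overall = round(overall, 1),
       n = nrow(m),
       item_means_raw = item_means,
       overall_raw = overall)
}

#' Summarize user-satisfaction survey responses
#'
#' One 5-point item per app function; satisfaction is reported per
#' function and deliberately not averaged into a single score.
#'
#' @param responses Matrix or data frame, one row per respondent, one
#'   column per function (default column names cover the six app
#'   functions).
#' @return List with `item_means` (named, rounded to 1 decimal) and `n`.
#' @export
summarize_satisfaction <- function(responses) {
  m <- as.matrix(responses)
  if (nrow(m) == 0L) stopf("empty response collection")
  if (any(is.na(m)) || any(m < 1) || any(m > 5))
    stopf("satisfaction items must lie in [1, 5]")
  if (is.null(colnames(m)))
    colnames(m) <- c("bp_recording", "medication_recording", "data_sending",
                     "alerting", "recommending",
                     "medication_education")[seq_len(ncol(m))]
  list(item_means = round(colMeans(m), 1), n = nrow(m))
}

#' Cronbach's alpha
#'
#' Internal-consistency utility for questionnaire item matrices. Provided
#' as a convenience; no reliability claims are attached to the bundled
#' instruments.
#'
#' @param responses Matrix or data frame, respondents in rows, items in
#'   columns (at least 2 items and 2 respondents).
#' @return Alpha coefficient (numeric scalar).
#' @export
cronbach_alpha <- function(responses) {
  m <- as.matrix(as.data.frame(responses))
  if (nrow(m) < 2L || ncol(m) < 2L)
    stopf("need at least 2 respondents and 2 items")
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / stats::var(rowSums(m)))
}
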