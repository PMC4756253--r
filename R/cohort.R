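# Synthetic pre/post adherence cohorts. MMS totals are modelled as sums
# of 6 exchangeable Bernoulli items: a beta-binomial whose mean matches
# the requested mean exactly and whose item-level intraclass correlation
# is calibrated to the requested SD (overdispersion relative to the plain
# binomial). Pre/post pairing goes through a Gaussian copula on a shared
# latent adherence propensity with correlation rho.

betabinom_pmf <- function(k, mean, sd) {
  p <- mean / k
  v <- sd^2
  if (p < 0 || p > 1) stopf("mean %s is outside the [0, %d] support", mean, k)
  base <- k * p * (1 - p)
  vmax <- mean * (k - mean)   # two-point mass at 0 and k
  if (v > vmax + 1e-9)
    stopf("sd %s infeasible on [0, %d] at mean %s; max sd is %.4g",
          sd, k, mean, sqrt(vmax))
  if (abs(v - base) < 1e-12 || base == 0) {
    return(stats::dbinom(0:k, k, p))
  }
  if (v < base)
    stopf(paste0("sd %s is below the binomial sd %.4g at mean %s; the ",
                 "item model only produces sd 0 or sd >= binomial"),
          sd, sqrt(base), mean)
  icc <- (v / base - 1) / (k - 1)
  if (icc >= 1)
    stopf("sd %s requires item correlation >= 1 at mean %s", sd, mean)
  a <- p * (1 - icc) / icc
  b <- (1 - p) * (1 - icc) / icc
  x <- 0:k
  pmf <- exp(lchoose(k, x) + lbeta(x + a, k - x + b) - lbeta(a, b))
  pmf / sum(pmf)
}

q_discrete <- function(u, pmf) {
  cdf <- cumsum(pmf)
  findInterval(u, cdf, left.open = FALSE) # values 0..k
}

#' Generate a synthetic paired pre/post adherence cohort
#'
#' Draws `n` paired Modified-Morisky-Scale totals (integers 0-6) whose
#' population means and SDs match the requested values (a calibrated
#' beta-binomial item model; the mean is matched exactly, the SD as
#' closely as the discrete 0-6 support allows). Pairing uses a shared
#' latent adherence propensity: the pre and post latent normals have
#' correlation `rho` and each margin is mapped through its calibrated
#' discrete quantile function, so the marginal distributions are
#' unaffected by the pairing.
#'
#' `sd = 0` with an integer mean produces a degenerate constant cohort.
#' An SD below the binomial SD at the requested mean (other than 0) is
#' not representable by the item model and raises an error stating the
#' feasible range.
#'
#' @param n Cohort size.
#' @param pre_mean,pre_sd,post_mean,post_sd Requested marginal moments on
#'   the 0-6 score scale.
#' @param rho Latent pairing correlation in \[-1, 1\] (default 0.5).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return An object of class `hma_cohort`: list with `n`, integer
#'   vectors `pre` and `post`, `seed` and the requested `params`.
#' @examples
#' ch <- generate_cohort(100, 4.2, 1.3, 5.2, 1.1, seed = 1)
#' range(ch$pre)  # within 0..6
#' @export
generate_cohort <- function(n, pre_mean, pre_sd, post_mean, post_sd,
                            rho = 0.5, seed) {
  stopifnot(n >= 1, abs(rho) <= 1)
  draw <- function(u, mean, sd) {
    if (sd == 0) {
      if (abs(mean - round(mean)) > 1e-9)
        stopf("sd = 0 requires an integer mean, got %s", mean)
      return(rep(as.integer(round(mean)), length(u)))
    }
    q_discrete(u, betabinom_pmf(6L, mean, sd))
  }
  ## validate moments before consuming randomness
  if (pre_sd > 0) betabinom_pmf(6L, pre_mean, pre_sd)
  if (post_sd > 0) betabinom_pmf(6L, post_mean, post_sd)

  set.seed(as.integer(seed))
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  structure(list(
    n = as.integer(n),
    pre = as.integer(draw(stats::pnorm(z1), pre_mean, pre_sd)),
    post = as.integer(draw(stats::pnorm(z2), post_mean, post_sd)),
    seed = as.integer(seed),
    params = list(pre_mean = pre_mean, pre_sd = pre_sd,
                  post_mean = post_mean, post_sd = post_sd, rho = rho)
  ), class = "hma_cohort")
}

#' @export
print.hma_cohort <- function(x, ...) {
  cat(sprintf("<hma_cohort> n = %d, pre %.2f (%.2f), post %.2f (%.2f)\n",
              x$n, mean(x$pre), stats::sd(x$pre), mean(x$post),
              stats::sd(x$post)))
  invisible(x)
}

#' Summarize a paired pre/post cohort
#'
#' Descriptive statistics plus the paired Wilcoxon signed-rank test on
#' the pre/post score pairs.
#'
#' @param cohort An [generate_cohort()] result (or any list with equal
#'   `pre`/`post` integer score vectors).
#' @param exact_cutover Passed to [wilcoxon_signed_rank()].
#' @return An object of class `hma_study_result` with `n`, `pre_mean`,
#'   `pre_sd`, `post_mean`, `post_sd`, `wilcoxon_statistic`, `p_value`
#'   and `n_effective`.
#' @export
summarize_study <- function(cohort, exact_cutover = 12) {
  stopifnot(length(cohort$pre) == length(cohort$post))
  w <- suppressWarnings(
    wilcoxon_signed_rank(cohort$pre, cohort$post,
                         exact_cutover = exact_cutover))
  structure(list(
    n = length(cohort$pre),
    pre_mean = mean(cohort$pre), pre_sd = stats::sd(cohort$pre),
    post_mean = mean(cohort$post), post_sd = stats::sd(cohort$post),
    wilcoxon_statistic = w$statistic,
    p_value = w$p_value,
    n_effective = w$n_effective,
    method = w$method,
    all_zero = w$all_zero
  ), class = "hma_study_result")
}

#' @export
print.hma_study_result <- function(x, ...) {
  cat(sprintf("paired study, n = %d: pre %.1f (%.1f) -> post %.1f (%.1f)\n",
              x$n, x$pre_mean, x$pre_sd, x$post_mean, x$post_sd))
  cat(sprintf("  Wilcoxon V = %g, p = %.4g (n_eff = %d, %s)\n",
              x$wilcoxon_statistic, x$p_value, x$n_effective, x$method))
  invisible(x)
}

#' Enrollment attrition summary
#'
#' Retention percentages from printed enrollment counts (whole-percent
#' rounding, as study reports print them).
#'
#' @param enrolled Number enrolled.
#' @param completed Number completing the post-test.
#' @param surveyed Optional number completing the usability survey.
#' @return List with `retention_pct`, `dropout_pct` and, if given,
#'   `survey_pct`.
#' @examples
#' attrition_summary(38, 29)$retention_pct  # 76
#' @export
attrition_summary <- function(enrolled, completed, surveyed = NULL) {
  stopifnot(enrolled >= completed)
  out <- list(enrolled = enrolled, completed = completed,
              retention_pct = round(100 * completed / enrolled),
              dropout_pct = round(100 * (enrolled - completed) / enrolled))
  if (!is.null(surveyed)) out$survey_pct <- round(100 * surveyed / enrolled)
  out
}
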