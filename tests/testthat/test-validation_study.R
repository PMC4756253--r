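test_that("decision nodes enumerate target branch points and evaluations", {
  nodes <- enumerate_decision_nodes(kb_default)
  ids <- vapply(nodes, `[[`, character(1), "node_id")
  # 3 profile-dependent target rule groups + 8 item evaluation nodes
  expect_length(nodes, 11)
  expect_setequal(ids[startsWith(ids, "target:")],
                  c("target:blood_pressure", "target:alcohol",
                    "target:waist_circumference"))
  # unconditional rule groups (e.g. smoking) contribute no target node
  expect_false("target:smoking" %in% ids)

  stress <- nodes[[which(ids == "evaluation:stress")]]
  expect_equal(stress$branches, c("low", "moderate", "high"))
  waist <- nodes[[which(ids == "target:waist_circumference")]]
  expect_equal(waist$branches, c("WC.male", "WC.else"))
})

test_that("coverage reports the fraction of branches exercised", {
  expect_equal(coverage(list(), kb_default)$coverage_fraction, 0)

  prof <- patient_profile("female", 45, 1.60, 55)
  one <- scenario("S1", prof, all_on_target_measurements())
  rep <- coverage(list(one), kb_default)
  # one scenario takes exactly one branch per node
  expect_equal(nrow(rep$covered), 11)
  expect_equal(nrow(rep$covered) + nrow(rep$uncovered), rep$n_branches)
  expect_equal(rep$n_branches, 23)

  # unevaluable scenarios are listed, not fatal
  bad <- scenario("S2", prof, measurements(waist = 90))
  rep2 <- coverage(list(one, bad), kb_default)
  expect_equal(rep2$unevaluable, "S2")
  expect_equal(nrow(rep2$covered), 11)
})

reduce_kb <- function(kb, items) {
  kb$items <- Filter(function(it) it$id %in% items, kb$items)
  kb$target_rules <- Filter(function(g) g$item %in% items, kb$target_rules)
  kb$evaluation_rules <- Filter(function(er) er$item %in% items,
                                kb$evaluation_rules)
  kb$recommendation_templates <-
    Filter(function(tp) tp$item %in% items, kb$recommendation_templates)
  kb
}

test_that("build_covering_suite reaches full coverage with few scenarios", {
  suite <- build_covering_suite(kb_default)
  rep <- attr(suite, "coverage")
  expect_equal(rep$coverage_fraction, 1.0)
  expect_lte(length(suite), 7)
  # information-theoretic lower bound: at least max branch count per node
  nodes <- enumerate_decision_nodes(kb_default)
  expect_gte(length(suite),
             max(vapply(nodes, function(nd) length(nd$branches), integer(1))))

  # removing any scenario from this minimal suite loses coverage
  for (i in seq_along(suite)) {
    rest <- suite[-i]
    expect_lt(coverage(rest, kb_default)$coverage_fraction, 1.0)
  }
})

test_that("suite construction adapts to reduced knowledge bases", {
  stress_only <- reduce_kb(kb_default, "stress")
  s1 <- build_covering_suite(stress_only)
  expect_length(s1, 3)  # one scenario per stress level
  expect_equal(attr(s1, "coverage")$coverage_fraction, 1.0)

  waist_only <- reduce_kb(kb_default, "waist_circumference")
  s2 <- build_covering_suite(waist_only)
  # male/female target branches and maintain/modify fit in two scenarios
  expect_length(s2, 2)
  expect_equal(attr(s2, "coverage")$coverage_fraction, 1.0)
})

test_that("wilcoxon reproduces the all-positive small-sample exact tail", {
  w <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 7))
  expect_equal(w$n_effective, 5)
  expect_equal(w$statistic, 15)
  expect_equal(w$p_value, 0.0625)  # 2 * 1/32
  expect_equal(w$method, "exact")

  expect_warning(w0 <- wilcoxon_signed_rank(1:4, 1:4), "zero")
  expect_equal(w0$p_value, 1.0)
  expect_true(w0$all_zero)
})

test_that("exact branch equals brute-force sign-pattern enumeration", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(3:10, 1)
    d <- sample(-4:4, n, replace = TRUE)
    if (all(d == 0)) d[1] <- 1
    w <- suppressWarnings(wilcoxon_signed_rank(d))
    expect_equal(w$p_value, brute_force_wilcoxon_p(d), tolerance = 1e-12,
                 info = paste(d, collapse = ","))
  }
})

test_that("tie-free exact p matches the reference implementation", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:10, 1)
    d <- sample(1:50, n) * sample(c(-1, 1), n, replace = TRUE)  # no |d| ties
    ours <- wilcoxon_signed_rank(d)
    ref <- stats::wilcox.test(d, exact = TRUE)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("large-sample branch matches the normal approximation oracle", {
  set.seed(43)
  d <- sample(c(-3:-1, 1:5), 40, replace = TRUE)
  ours <- wilcoxon_signed_rank(d)
  expect_equal(ours$method, "normal")
  ref <- stats::wilcox.test(d, exact = FALSE, correct = FALSE)
  expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-10)
})

test_that("cohort generator hits the requested moments and is reproducible", {
  a <- generate_cohort(500, 4.2, 1.3, 5.2, 1.1, seed = 99)
  b <- generate_cohort(500, 4.2, 1.3, 5.2, 1.1, seed = 99)
  expect_identical(a$pre, b$pre)
  expect_identical(a$post, b$post)
  expect_true(all(a$pre %in% 0:6) && all(a$post %in% 0:6))

  big <- generate_cohort(1e5, 4.2, 1.3, 5.2, 1.1, seed = 7)
  tol <- 3 * 1.3 / sqrt(1e5)
  expect_lt(abs(mean(big$pre) - 4.2), tol)
  expect_lt(abs(mean(big$post) - 5.2), 3 * 1.1 / sqrt(1e5))
  expect_lt(abs(sd(big$pre) - 1.3), 0.05)

  const <- generate_cohort(50, 4, 0, 5, 0, seed = 1)
  expect_true(all(const$pre == 4) && all(const$post == 5))

  expect_error(generate_cohort(10, 4.2, 0.5, 5.2, 1.1, seed = 1),
               "below the binomial sd")
  expect_error(generate_cohort(10, 4.2, 3.0, 5.2, 1.1, seed = 1),
               "infeasible")
})

test_that("paired latent propensity induces positive pre/post correlation", {
  ch <- generate_cohort(2e4, 4.2, 1.3, 5.2, 1.1, rho = 0.5, seed = 3)
  expect_gt(cor(ch$pre, ch$post), 0.25)
  ind <- generate_cohort(2e4, 4.2, 1.3, 5.2, 1.1, rho = 0, seed = 3)
  expect_lt(abs(cor(ind$pre, ind$post)), 0.05)
})

test_that("study summary detects the simulated adherence improvement", {
  up <- list(pre = rep(c(3, 4, 5), length.out = 29))
  up$post <- up$pre + 1
  s <- summarize_study(up)
  expect_gt(s$wilcoxon_statistic, 0)
  expect_lt(s$p_value, 0.001)

  flat <- list(pre = up$pre, post = up$pre)
  expect_equal(summarize_study(flat)$p_value, 1.0)

  # power at the deployment-scale parameters: median p over seeds < 0.05
  ps <- vapply(1:200, function(s) {
    summarize_study(generate_cohort(29, 4.2, 1.3, 5.2, 1.1, rho = 0.5,
                                    seed = 1000 + s))$p_value
  }, numeric(1))
  expect_lt(median(ps), 0.05)
})

test_that("attrition summary reproduces printed retention percentages", {
  at <- attrition_summary(38, 29, surveyed = 19)
  expect_equal(at$retention_pct, 76)
  expect_equal(at$dropout_pct, 24)
  expect_equal(at$survey_pct, 50)
})
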