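test_that("descriptive summaries follow the mean/median/count conventions", {
  s <- summarize_variable(c(1, 2, 3, 4, 5), "nonnormal")
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)

  s <- summarize_variable(rep(4.2, 10), "normal")
  expect_equal(s$mean, 4.2)
  expect_equal(s$sd, 0)

  s <- summarize_variable(c(rep(TRUE, 20), rep(FALSE, 121)),
                          "categorical")
  expect_equal(s$count, 20)
  expect_equal(round(s$pct, 1), 14.2)
  expect_identical(s$label, "20 (14.2%)")

  expect_error(summarize_variable(numeric(), "normal"), "no non-missing")

  # percentile rule is configurable
  s6 <- summarize_variable(c(1, 2, 3, 4, 5), "nonnormal",
                           ccta_config(quantile_type = 6))
  expect_equal(c(s6$q1, s6$q3), c(1.5, 4.5))
})

test_that("two-group comparison is exact by enumeration at small n", {
  res <- compare_two(c(1, 2, 3), c(4, 5, 6))
  expect_true(res$exact)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)

  same <- compare_two(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  tied <- compare_two(c(1, 2), c(1, 2))
  expect_true(is.finite(tied$statistic))
  expect_lte(tied$p_value, 1)
  expect_equal(tied$p_value, oracle_mwu_exact(c(1, 2), c(1, 2)))

  expect_error(compare_two(numeric(), 1:3), "non-empty")
})

test_that("exact enumeration matches the independent oracle on random small samples", {
  set.seed(11)
  for (i in 1:30) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(1:6, n1, replace = TRUE)  # ties likely
    y <- sample(1:6, n2, replace = TRUE)
    expect_equal(compare_two(x, y)$p_value, oracle_mwu_exact(x, y),
                 info = sprintf("case %d", i))
  }
})

test_that("normal approximation stays close to the exact p at small n", {
  set.seed(12)
  cfg_asym <- ccta_config(exact_max_n = 2)  # force the asymptotic path
  for (i in 1:25) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    x <- runif(n1); y <- runif(n2)  # continuous, no heavy ties
    p_exact <- compare_two(x, y)$p_value
    p_asym <- compare_two(x, y, cfg_asym)$p_value
    expect_lt(abs(p_exact - p_asym), 0.05)
  }
})

test_that("multi-group comparison emits the omnibus and all Bonferroni pairs", {
  set.seed(13)
  groups <- list(a = rnorm(20), b = rnorm(20, 1), c = rnorm(20, 2),
                 d = rnorm(20))
  res <- compare_multi(groups, posthoc = TRUE)
  expect_length(res, 1 + 6)
  pairs <- res[-1]
  labels <- t(vapply(pairs, `[[`, character(2), "pair"))
  expect_equal(nrow(unique(labels)), 6)
  for (r in pairs) {
    expect_gte(r$p_value, r$p_raw)
    expect_equal(r$p_value, min(1, 6 * r$p_raw))
    expect_lte(r$p_value, 1)
  }

  # identical groups: all adjusted post-hoc p-values are 1
  flat <- compare_multi(list(a = c(1, 2, 3), b = c(1, 2, 3),
                             c = c(1, 2, 3)), posthoc = TRUE)
  for (r in flat[-1]) expect_equal(r$p_value, 1)

  expect_error(compare_multi(list(a = 1:3)), "length")
  expect_error(compare_multi(list(a = 1:3, b = numeric())), "non-empty")
})

test_that("with two groups the omnibus agrees with the two-group test", {
  set.seed(14)
  x <- rnorm(30); y <- rnorm(30, 0.6)
  kw <- compare_multi(list(x = x, y = y))[[1]]
  mw <- compare_two(x, y, ccta_config(exact_max_n = 2))
  expect_lt(abs(kw$p_value - mw$p_value), 0.02)
})

test_that("chi-squared is Pearson without continuity correction", {
  hom <- compare_categorical(matrix(c(10, 10, 10, 10), 2))
  expect_equal(hom$statistic, 0)
  expect_equal(hom$p_value, 1)

  tab <- matrix(c(1, 20, 73, 121), 2)  # a, c, b, d
  a <- 1; b <- 73; c <- 20; d <- 121; n <- a + b + c + d
  byhand <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  res <- compare_categorical(tab)
  expect_equal(res$statistic, byhand, tolerance = 1e-12)
  expect_equal(round(res$statistic, 2), 9.07)

  # small expected counts warn but never auto-switch tests
  expect_warning(compare_categorical(matrix(c(1, 2, 2, 1), 2)),
                 "expected counts")

  big <- compare_categorical(matrix(c(30, 40, 25, 35, 20, 30, 15, 25),
                                    2))
  expect_equal(big$df, 3)
  expect_error(compare_categorical(matrix(0, 2, 2)), "positive total")
})

test_that("dichotomization uses strict thresholds", {
  panel <- score_patient(worked_example(),
                         ccta_config(rounding = "paper_2dp"))
  flags <- dichotomize_panel(panel)
  expect_true(flags$sis_high)
  expect_true(flags$sss_high)
  expect_true(flags$lesc_high)
  expect_false(flags$os)

  at <- data.frame(patient_id = "t", sis = 3, sss = 5, ct_lesc = 8.7,
                   has_obstructive = FALSE)
  expect_false(any(unlist(dichotomize_panel(at)[-1])))

  zero <- data.frame(patient_id = "z", sis = 0, sss = 0, ct_lesc = 0,
                     has_obstructive = FALSE)
  expect_false(any(unlist(dichotomize_panel(zero)[-1])))
})

test_that("logistic odds ratios match the 2x2 closed form with Wald intervals", {
  set.seed(15)
  for (i in 1:10) {
    a <- sample(3:30, 1); b <- sample(3:30, 1)
    c_ <- sample(3:30, 1); d <- sample(3:30, 1)
    outcome <- c(rep(TRUE, a), rep(FALSE, b), rep(TRUE, c_),
                 rep(FALSE, d))
    group <- rep(c("exposed", "reference"), c(a + b, c_ + d))
    res <- logistic_or(outcome, group, reference = "reference")
    or_hand <- (a * d) / (b * c_)
    se_hand <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
    expect_equal(res$or, or_hand, tolerance = 1e-4)
    expect_equal(res$ci_lower, exp(log(or_hand) - 1.96 * se_hand),
                 tolerance = 1e-3)
    expect_equal(res$ci_upper, exp(log(or_hand) + 1.96 * se_hand),
                 tolerance = 1e-3)
    expect_false(res$separation)
  }
})

test_that("logistic regression flags equal odds and separation", {
  outcome <- rep(c(TRUE, FALSE, TRUE, FALSE), c(10, 30, 5, 15))
  group <- rep(c("g1", "g2"), c(40, 20))
  res <- logistic_or(outcome, group, reference = "g1")
  expect_equal(res$or, 1, tolerance = 1e-6)

  sep_out <- rep(c(FALSE, TRUE, FALSE), c(20, 10, 10))
  sep_grp <- rep(c("ref", "all_or_nothing"), c(20, 20))
  res <- logistic_or(sep_out, sep_grp, reference = "ref")
  expect_true(res$separation)
  expect_true(is.na(res$or))

  expect_error(logistic_or(rep(FALSE, 10), rep(c("a", "b"), 5), "a"),
               "does not vary")
})

test_that("lesion tabulation conserves counts across margins", {
  fig <- worked_example()
  lesions <- data.frame(patient_id = fig$patient_id,
                        fig$lesions, stringsAsFactors = FALSE)
  tab <- tabulate_lesions(lesions, rep("dm", nrow(lesions)))
  expect_equal(sum(tab$segments), 6)
  expect_equal(unname(tab$severity["non_obstructive", "dm"]), 6)
  expect_equal(unname(tab$severity["obstructive", "dm"]), 0)
  expect_equal(unname(tab$composition["calcified", "dm"]), 3)
  expect_equal(unname(tab$composition["non_calcified_or_mixed", "dm"]), 3)

  # random cohort: severity and composition margins match segment totals
  set.seed(16)
  cohort <- generate_cohort(sim_config(
    seed = 16, profiles = default_profiles(n = c(15, 15, 15, 15))))
  grp <- setNames(cohort$clinical$group, cohort$clinical$patient_id)
  tab <- tabulate_lesions(cohort$lesions, grp)
  expect_equal(colSums(tab$severity), tab$totals)
  expect_equal(colSums(tab$composition), tab$totals)
  expect_equal(colSums(tab$segments), tab$totals)
})
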