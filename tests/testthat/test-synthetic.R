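test_that("profile validation lists every violation", {
  expect_error(group_profile("x", 10, dominance_probs = c(1, 1, 1)),
               "dominance_probs")
  expect_error(group_profile("x", 10, lesion_prob = 2), "lesion_prob")
  err <- tryCatch(group_profile("x", -1, severity_probs = c(1, 1, 0),
                                risk_range = c(9, 2)),
                  error = conditionMessage)
  expect_match(err, "severity_probs")
  expect_match(err, "risk_range")
  expect_match(err, "n_patients")
})

test_that("degenerate profiles hit the score boundaries", {
  set.seed(21)
  none <- group_profile("none", 1, lesion_prob = 0, dm = FALSE,
                        risk_range = c(0, 5))
  gp <- generate_patient(none, "z1")
  panel <- score_patient(gp$ccta)
  expect_equal(panel$sis, 0L)
  expect_equal(panel$sc, 0)

  allsev <- group_profile("sat", 1, lesion_prob = 1,
                          severity_probs = c(0, 0, 1))
  gp <- generate_patient(allsev, "s1")
  panel <- score_patient(gp$ccta)
  expect_equal(panel$sis,
               length(applicable_segments(gp$ccta$dominance)))
  expect_equal(panel$sss, 3L * panel$sis)
  expect_true(panel$spp_positive)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 99,
                    profiles = default_profiles(n = c(8, 8, 8, 8)))
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$lesions, c2$lesions)

  c3 <- generate_cohort(sim_config(
    seed = 100, profiles = default_profiles(n = c(8, 8, 8, 8))))
  expect_false(identical(c1$lesions, c3$lesions))
})

test_that("group sizes, labels and eligibility contracts hold", {
  cohort <- generate_cohort(sim_config(
    seed = 5, profiles = default_profiles(n = c(12, 6, 7, 9))))
  expect_equal(nrow(cohort$clinical), 34)
  expect_equal(as.vector(table(factor(
    cohort$clinical$group,
    levels = c("control", "low", "moderate", "high")))),
    c(12, 6, 7, 9))

  # every patient passes anatomical validation
  for (p in cohort$patients) expect_identical(validate_patient(p),
                                              character())
  # DM-group records meet the diagnostic and eligibility rules
  dm <- cohort$clinical[cohort$clinical$group != "control", ]
  expect_true(all(meets_t2dm_criteria(dm)))
  expect_true(all(is_eligible_dm(dm)$eligible))
  # UKPDS risk bands land in the intended tiers
  expect_identical(
    as.character(stratify_risk(dm$ukpds_fatal_risk_pct)),
    dm$group)
})

test_that("empirical frequencies recover the configured profile", {
  profiles <- default_profiles(n = c(500, 500, 500, 500))
  cohort <- generate_cohort(sim_config(seed = 31, profiles = profiles))
  est <- recover_profile(cohort)
  for (g in names(profiles)) {
    prof <- profiles[[g]]
    e <- est[[g]]
    n_trials <- e$n_patients * 16  # applicable segments per dominance
    tol <- 3 * sqrt(prof$lesion_prob * (1 - prof$lesion_prob) /
                      n_trials)
    expect_lt(abs(e$lesion_prob - prof$lesion_prob), tol)
    for (k in 1:3) {
      p <- prof$severity_probs[k]
      tol_k <- 3 * sqrt(p * (1 - p) / e$n_lesions)
      expect_lt(abs(e$severity_probs[k] - p), tol_k + 1e-9)
      q <- prof$composition_probs[k]
      tol_q <- 3 * sqrt(q * (1 - q) / e$n_lesions)
      expect_lt(abs(e$composition_probs[k] - q), tol_q + 1e-9)
    }
  }
})

test_that("empty groups are flagged rather than estimated", {
  profiles <- default_profiles(n = c(5, 5, 5, 5))
  profiles$empty <- group_profile("empty", 0)
  cohort <- generate_cohort(sim_config(seed = 8, profiles = profiles))
  expect_false("empty" %in% cohort$clinical$group)

  # degenerate all-severe profile recovers severity mix (0, 0, 1)
  sat <- generate_cohort(sim_config(seed = 9, profiles = list(
    sat = group_profile("sat", 30, lesion_prob = 0.5,
                        severity_probs = c(0, 0, 1)))))
  est <- recover_profile(sat)$sat
  expect_equal(est$severity_probs, c(0, 0, 1))
})

test_that("moderate and high tiers separate from control through the pipeline", {
  cohort <- generate_cohort(sim_config(
    seed = 42, profiles = default_profiles(n = c(200, 200, 200, 200))))
  scores <- score_cohort(cohort$patients)
  grp <- factor(cohort$clinical$group,
                levels = c("control", "low", "moderate", "high"))
  for (v in c("sis", "sss", "ct_lesc")) {
    by_grp <- split(scores[[v]], grp)
    omnibus <- compare_multi(by_grp)[[1]]
    expect_lt(omnibus$p_value, 0.05)
    meds <- vapply(by_grp, median, numeric(1))
    expect_gt(meds[["moderate"]], meds[["control"]])
    expect_gt(meds[["high"]], meds[["control"]])
  }
})
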