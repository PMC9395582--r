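test_that("stenosis grading follows the obstructive and severe cuts", {
  expect_identical(grade_lesion(c(30, 49.9, 50, 60, 70, 70.1, 71, 100)),
                   c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L))
  expect_error(grade_lesion(101), "\\[0, 100\\]")
  expect_error(grade_lesion(-1), "\\[0, 100\\]")
  # boundaries are configuration, not constants
  cfg <- ccta_config(obstructive_cut = 40, severe_cut = 60)
  expect_identical(grade_lesion(c(39, 40, 60, 61), cfg),
                   c(1L, 2L, 2L, 3L))
})

test_that("obstructive stenosis is >= 50% and matches grade >= 2", {
  expect_identical(is_obstructive(c(49.9, 50, 100)),
                   c(FALSE, TRUE, TRUE))
  pct <- seq(0, 100, by = 0.5)
  expect_identical(is_obstructive(pct), grade_lesion(pct) >= 2L)
})

test_that("SIS, SSS, SC compose as count, graded sum and ratio", {
  p <- worked_example()
  expect_equal(compute_sis(p), 6)
  expect_equal(compute_sss(p), 6)
  expect_equal(compute_sc(6, 6), 1)
  expect_equal(compute_sc(0, 0), 0)
  expect_equal(compute_sc(4, 10), 2.5)
  expect_error(compute_sc(0, 3), "SSS must be 0")
  expect_error(compute_sc(2, 7), "inconsistent")

  empty <- ccta_patient("none", "right")
  expect_equal(compute_sis(empty), 0)
  expect_equal(compute_sss(empty), 0)

  mixed3 <- ccta_patient("m3", "right", data.frame(
    segment = c("rca_proximal", "rca_mid", "rca_distal"),
    stenosis_pct = c(30, 60, 80),
    composition = "calcified"))
  expect_equal(compute_sss(mixed3), 1 + 2 + 3)

  # fully diseased balanced-dominance patient: one lesion per
  # applicable segment, all severe
  segs <- applicable_segments("balanced")
  full <- ccta_patient("full", "balanced", data.frame(
    segment = segs, stenosis_pct = 90, composition = "mixed"))
  expect_equal(compute_sis(full), length(segs))
  expect_equal(compute_sss(full), 3 * length(segs))
})

test_that("SPP needs a severe lesion in the left main or a proximal segment", {
  expect_false(compute_spp(worked_example()))
  spp_pos <- ccta_patient("s", "right", data.frame(
    segment = "lad_proximal", stenosis_pct = 80, composition = "mixed"))
  expect_true(compute_spp(spp_pos))
  mid <- ccta_patient("m", "right", data.frame(
    segment = "lad_mid", stenosis_pct = 80, composition = "mixed"))
  expect_false(compute_spp(mid))
  # 70% exactly is grade 2, not severe, hence not SPP-qualifying
  at_70 <- ccta_patient("b", "right", data.frame(
    segment = "left_main", stenosis_pct = 70, composition = "mixed"))
  expect_false(compute_spp(at_70))
})

test_that("per-lesion CT-LeSc multiplies weight, composition and stenosis factors", {
  expect_equal(lesion_ct_lesc("left_main", "mixed", 30, "right"), 4.6125)
  expect_equal(lesion_ct_lesc("lcx_proximal", "calcified", 30, "right"),
               0.9225)
  expect_equal(lesion_ct_lesc("lad_proximal", "calcified", 60, "right"),
               3.5)
  expect_error(lesion_ct_lesc("pda", "mixed", 30, "left"),
               class = "notApplicableSegment")
})

test_that("patient CT-LeSc sums partials under both rounding modes", {
  p <- worked_example()
  expect_equal(patient_ct_lesc(p, rounding = "paper_2dp"), 12.31)
  # exact sum: 4.6125 + 3.22875 + 2.30625 + 0.615 + 0.9225 + 0.615
  expect_equal(patient_ct_lesc(p, rounding = "full_precision"), 12.3)
  expect_equal(patient_ct_lesc(ccta_patient("e", "left")), 0)
})

test_that("the full panel composes the five scores and the OS flag", {
  panel <- score_patient(worked_example(),
                         ccta_config(rounding = "paper_2dp"))
  expect_equal(panel$sis, 6L)
  expect_equal(panel$sss, 6L)
  expect_equal(panel$sc, 1)
  expect_false(panel$spp_positive)
  expect_equal(panel$ct_lesc, 12.31)
  expect_false(panel$has_obstructive)
  expect_equal(unname(panel$partial_lesc),
               c(4.61, 3.23, 2.31, 0.62, 0.92, 0.62))

  empty <- score_patient(ccta_patient("none", "balanced"))
  expect_equal(unlist(empty[c("sis", "sss", "sc", "ct_lesc")]),
               c(sis = 0, sss = 0, sc = 0, ct_lesc = 0))
  expect_false(empty$spp_positive)
  expect_false(empty$has_obstructive)

  one <- score_patient(ccta_patient("one", "right", data.frame(
    segment = "left_main", stenosis_pct = 80, composition = "mixed")))
  expect_equal(one$sis, 1L)
  expect_equal(one$sss, 3L)
  expect_equal(one$sc, 3)
  expect_true(one$spp_positive)
  expect_equal(one$ct_lesc, 5 * 1.5 * 1)
  expect_true(one$has_obstructive)
})

test_that("scoring rejects invalid patients with a named violation", {
  bad <- ccta_patient("bad", "right", data.frame(
    segment = "pda_from_lca", stenosis_pct = 30, composition = "mixed"))
  expect_error(score_patient(bad), "fails validation")
  expect_error(compute_sis(bad), "not applicable")
})

test_that("CT-LeSc is additive over lesions at full precision", {
  set.seed(41)
  for (i in 1:25) {
    p <- random_patient(sprintf("add%d", i))
    singles <- vapply(seq_len(nrow(p$lesions)), function(j) {
      patient_ct_lesc(ccta_patient("s", p$dominance,
                                   p$lesions[j, , drop = FALSE]))
    }, numeric(1))
    expect_equal(patient_ct_lesc(p), sum(singles))
  }
})
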