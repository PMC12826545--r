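test_that("cohort generation follows the protocol structure", {
  co <- make_cohort(10, 10, seed = 99)
  expect_equal(nrow(co), 20)
  expect_equal(sum(co$dense), 10)
  acq <- cohort_acquisitions(co)
  expect_equal(nrow(acq), 240) # 20 subjects x 3 compressions x 4 angles
  expect_equal(sort(unique(acq$compression_mm)), c(0, 2, 5))
  expect_equal(sort(unique(acq$angle_deg)), c(0, 30, 60, 90))
  empty <- make_cohort(0, 0, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_error(make_cohort(-1, 2), ">= 0")
})

test_that("subject draws respect the configured distributions", {
  cfg <- cohort_config()
  co <- make_cohort(100, 100, cfg, seed = 123)
  expect_true(all(co$doa >= cfg$doa_range[1] & co$doa <= cfg$doa_range[2]))
  # distributional self-check of the DoA draw
  ks <- suppressWarnings(
    stats::ks.test(co$doa, "punif", cfg$doa_range[1], cfg$doa_range[2]))
  expect_gt(ks$p.value, 0.01)
  expect_equal(co$re_long / co$re_trans, co$doa, tolerance = 1e-12)
  expect_equal(co$rv_long / co$rv_trans, co$doa, tolerance = 1e-12)
  expect_true(all(co$aos_deg >= 0 & co$aos_deg < 180))
  # dense subjects stiffen more than non-dense on average
  expect_gt(min(co$stiffening_per_mm[co$dense]),
            max(0, min(co$stiffening_per_mm[!co$dense])))
  expect_gt(mean(co$stiffening_per_mm[co$dense]),
            mean(co$stiffening_per_mm[!co$dense]))
})

test_that("cohort and acquisitions are reproducible under the master seed", {
  a <- make_cohort(3, 3, seed = 7)
  b <- make_cohort(3, 3, seed = 7)
  expect_identical(a, b)
  cfg <- cohort_config()
  rf1 <- acquire_rf(a[2, ], 2, 30, cfg)
  rf2 <- acquire_rf(b[2, ], 2, 30, cfg)
  expect_identical(rf1$samples, rf2$samples)
  expect_equal(rf1$compression_mm, 2)
  expect_equal(rf1$angle_deg, 30)
})

test_that("isotropic configuration yields unit ground-truth DoA", {
  co <- make_cohort(2, 2, cohort_config(doa_range = c(1, 1)), seed = 5)
  expect_equal(co$doa, rep(1, 4))
  expect_equal(co$re_long, co$re_trans)
})

test_that("ground truth maps compression and angle onto the moduli", {
  co <- make_cohort(1, 1, seed = 31)
  cfg <- cohort_config()
  gt <- cohort_ground_truth(co, cfg)
  expect_equal(nrow(gt), 2 * 3 * 4)
  s <- co[1, ]
  row <- dplyr::filter(gt, subject_id == s$subject_id,
                       compression_mm == 5, angle_deg == 60)
  expect_equal(row$gt_re,
               modulus_at_angle(s$re_long, s$re_trans, s$aos_deg, 60) *
                 (1 + s$stiffening_per_mm)^5, tolerance = 1e-12)
})
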