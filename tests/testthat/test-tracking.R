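tm <- visr_timing()
ne <- n_events(tm)

rigid_schedule <- function(shift_um) {
  matrix(c(0, 0, rep(shift_um, ne - 2)), nrow = 1)
}

test_that("identical reference and tracked lines give zero displacement, unit correlation", {
  rf <- small_rf(snr_db = Inf, disp_schedule = matrix(0, 1, ne))
  d <- ncc_track(rf)
  expect_true(all(abs(d$disp_um) < 1e-9, na.rm = TRUE))
  expect_true(all(d$corr > 0.999, na.rm = TRUE))
})

test_that("known rigid shifts are recovered with small bias and sub-micron jitter", {
  ph <- small_phantom(seed = 42)
  for (sh in c(2, 5, 10)) {
    rf <- small_rf(ph, snr_db = 20, seed = 7,
                   disp_schedule = rigid_schedule(sh))
    est <- ncc_track(rf)$disp_um[, 3:ne, ]
    expect_lt(abs(mean(est, na.rm = TRUE) - sh), 1)          # bias
    expect_lt(sd(est, na.rm = TRUE), 1)                      # jitter
  }
})

test_that("a one-sample shift (19.25 um at 40 MHz) is recovered on the integer lag", {
  rf <- small_rf(small_phantom(seed = 9), snr_db = 20, seed = 5,
                 disp_schedule = rigid_schedule(19.25))
  est <- ncc_track(rf)$disp_um[, 3:ne, ]
  expect_lt(abs(mean(est, na.rm = TRUE) - 19.25), 0.5)
})

test_that("displacement estimates are antisymmetric under shift sign reversal", {
  ph <- small_phantom(seed = 13)
  up <- ncc_track(small_rf(ph, snr_db = Inf, disp_schedule = rigid_schedule(6)))
  dn <- ncc_track(small_rf(ph, snr_db = Inf, disp_schedule = rigid_schedule(-6)))
  expect_equal(mean(up$disp_um[, 3:ne, ], na.rm = TRUE),
               -mean(dn$disp_um[, 3:ne, ], na.rm = TRUE), tolerance = 0.05)
})

test_that("tracking error grows as SNR decreases", {
  ph <- small_phantom(seed = 21)
  rms <- vapply(c(40, 20, 10), function(snr) {
    rf <- small_rf(ph, snr_db = snr, seed = 3,
                   disp_schedule = rigid_schedule(5))
    sqrt(mean((ncc_track(rf)$disp_um[, 3:ne, ] - 5)^2, na.rm = TRUE))
  }, numeric(1))
  expect_true(all(diff(rms) > 0))
})

test_that("static ensembles at 20 dB track below the noise floor after ensemble averaging", {
  rf <- small_rf(small_phantom(seed = 31), snr_db = 20, seed = 8,
                 disp_schedule = matrix(0, 1, ne))
  d <- ncc_track(rf)
  per_pixel <- apply(d$disp_um, c(1, 3), mean)
  expect_lt(mean(abs(per_pixel), na.rm = TRUE), 0.5)
})

test_that("estimates respect the search region and invalid kernels are flagged", {
  rf <- small_rf(snr_db = 20, seed = 2, disp_schedule = rigid_schedule(3))
  d <- ncc_track(rf)
  expect_true(all(abs(d$disp_um) <= 40 + 1e-9, na.rm = TRUE))
  expect_true(all(d$corr >= -1 & d$corr <= 1))
  # kernel longer than the A-line is rejected
  expect_error(ncc_track(rf, tracking_params(kernel_um = 1e6)), "A-line")
})

test_that("peak displacement is the curve maximum and scales linearly with force", {
  expect_equal(peak_displacement(rep(0, 10)), 0)
  expect_error(peak_displacement(numeric(0)), "empty")
  expect_true(is.na(peak_displacement(rep(NA_real_, 5))))
  curve <- msd_response(0.03, 0.012, tm)
  fine <- msd_response(0.03, 0.012, tm, t = seq(0, max(event_times(tm)),
                                                by = 1e-4))
  # event-grid PD is within one slow-time sample of the continuous maximum
  expect_lte(peak_displacement(curve), max(fine$disp_um))
  expect_equal(peak_displacement(curve), max(curve$disp_um))
  expect_equal(peak_displacement(2 * curve$disp_um),
               2 * peak_displacement(curve$disp_um))
  expect_gte(peak_displacement(curve), max(curve$disp_um) - 1e-12)
})
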