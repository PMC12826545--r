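tm <- visr_timing()

test_that("noise-free curves are recovered to optimizer tolerance", {
  for (p in list(c(0.03, 0.012), c(0.08, 0.02), c(0.01, 0.006))) {
    f <- fit_msd(msd_curve(p[1], p[2], tm), tm)
    expect_lt(abs(f$re - p[1]) / p[1], 1e-3)
    expect_lt(abs(f$rv - p[2]) / p[2], 1e-3)
    expect_lt(f$fit_error, 1e-3) # µm RMS
    expect_true(f$converged)
  }
})

test_that("noisy curves recover parameters within a few percent (Monte Carlo)", {
  true <- c(re = 0.03, rv = 0.012)
  base <- msd_curve(true[1], true[2], tm)
  sdn <- 0.05 * sqrt(mean(base^2))
  set.seed(1234)
  errs <- t(vapply(seq_len(200), function(i) {
    f <- fit_msd(base + rnorm(length(base), sd = sdn), tm)
    abs(c(f$re, f$rv) - true) / true
  }, numeric(2)))
  expect_lt(median(errs[, 1]), 0.05)
  expect_lt(median(errs[, 2]), 0.05)
})

test_that("scaling the curve rescales the fitted parameters inversely", {
  # doubling the applied force doubles the displacement; the per-unit-force
  # parameters halve (exact in the inertia-negligible regime)
  f1 <- fit_msd(msd_curve(0.03, 0.012, tm), tm)
  f2 <- fit_msd(2 * msd_curve(0.03, 0.012, tm), tm)
  expect_equal(f2$re, f1$re / 2, tolerance = 0.02)
  expect_equal(f2$rv, f1$rv / 2, tolerance = 0.02)
  expect_equal(f2$pd, 2 * f1$pd, tolerance = 1e-9)
})

test_that("degenerate curves are marked invalid", {
  flat <- fit_msd(rep(0, n_events(tm)), tm)
  expect_false(flat$converged)
  expect_true(is.na(flat$re))
  sparse <- rep(NA_real_, n_events(tm))
  sparse[3:8] <- 1
  expect_false(fit_msd(sparse, tm)$converged)
})

test_that("tidy and glance methods expose the fit", {
  f <- fit_msd(msd_curve(0.03, 0.012, tm), tm)
  td <- tidy(f)
  expect_equal(td$term, c("re", "rv"))
  gl <- glance(f)
  expect_named(gl, c("re", "rv", "pd_um", "fit_error_um", "converged"))
})

test_that("the grid engine agrees with the per-curve optimizer", {
  ph <- small_phantom(seed = 2, re = 0.05, rv = 0.018)
  d <- ncc_track(small_rf(ph, snr_db = 20, seed = 6))
  mg <- visr_image(d, engine = "grid")
  sel <- which(mg$valid, arr.ind = TRUE)
  sel <- sel[seq(1, nrow(sel), length.out = 12), , drop = FALSE]
  fit_idx <- seq(tm$n_reference + 1L, n_events(tm))
  for (k in seq_len(nrow(sel))) {
    curve <- d$disp_um[sel[k, 1], , sel[k, 2]]
    curve[d$corr[sel[k, 1], , sel[k, 2]] < 0.8] <- NA
    fo <- fit_msd(curve, tm)
    expect_equal(mg$re[sel[k, 1], sel[k, 2]], fo$re, tolerance = 0.05)
    expect_equal(mg$rv[sel[k, 1], sel[k, 2]], fo$rv, tolerance = 0.05)
  }
})

test_that("a homogeneous phantom yields uniform elasticity maps", {
  ph <- small_phantom(seed = 9, re = 0.04, rv = 0.015)
  m <- visr_image(ncc_track(small_rf(ph, snr_db = Inf, seed = 1)))
  vals <- m$re[focal_roi(m) & m$valid]
  expect_gt(length(vals), 50)
  expect_lt(sd(vals) / mean(vals), 0.10)
  expect_lt(abs(median(vals) - 0.04) / 0.04, 0.10)
})

test_that("a stiff-over-soft layered phantom preserves layer ordering", {
  mech <- dplyr::bind_rows(
    mech_layer(0.09, 0.09, 0.03, 0.03, z_top_mm = -Inf, z_bot_mm = 20),
    mech_layer(0.03, 0.03, 0.012, 0.012, z_top_mm = 20, z_bot_mm = Inf))
  ph <- tissue_phantom(mech, seed = 8, z_range_mm = c(14, 30),
                       lat_range_mm = c(-3.2, 3.2), n_lines = 10, fov_mm = 5)
  m <- visr_image(ncc_track(small_rf(ph, snr_db = 20, seed = 3)))
  td <- tidy(m)
  stiff <- td$re[td$axial_mm < 19.5 & td$valid]
  soft <- td$re[td$axial_mm > 20.5 & td$valid]
  expect_gt(median(stiff, na.rm = TRUE), median(soft, na.rm = TRUE))
})

test_that("an empty valid mask propagates", {
  rf <- small_rf(snr_db = 20, seed = 2)
  d <- ncc_track(rf)
  d$corr[] <- 0 # all estimates invalid
  m <- visr_image(d)
  expect_false(any(m$valid))
  expect_true(all(is.na(m$re)))
})
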