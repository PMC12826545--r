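geom_default <- list(axial_mm = seq(14, 26, by = 0.094),
                     lateral_mm = seq(-9.75, 9.75, length.out = 40))

test_that("focal ROI includes the focus and excludes beyond the half-widths", {
  spec <- roi_spec()
  m <- focal_roi(geom_default, spec)
  at <- function(z, x) m[which.min(abs(geom_default$axial_mm - z)),
                         which.min(abs(geom_default$lateral_mm - x))]
  expect_true(at(20, 0))
  expect_false(at(23.5, 0))   # 3.5 mm > 3 mm axially
  expect_false(at(20, 3.6))   # beyond lateral half-width
  # exhaustive enumeration oracle for the mask pixel count
  brute <- 0
  for (z in geom_default$axial_mm) {
    for (x in geom_default$lateral_mm) {
      if (abs(z - 20) <= 3 && abs(x - 0) <= 3) brute <- brute + 1
    }
  }
  expect_equal(sum(m), brute)
  expect_identical(m, focal_roi(geom_default, spec)) # deterministic
})

test_that("focal ROI outside the imaged region errors", {
  geom <- list(axial_mm = seq(30, 40, by = 0.094),
               lateral_mm = geom_default$lateral_mm)
  expect_error(focal_roi(geom, roi_spec()), "outside")
})

test_that("matched ROI translates then clips to the focal band", {
  spec <- roi_spec()
  m <- matched_roi(geom_default, spec, 2) # [15,21] clipped to [17,23] -> [17,21]
  z <- geom_default$axial_mm[rowSums(m) > 0]
  expect_gte(min(z), 17)
  expect_lte(max(z), 21)
  expect_identical(matched_roi(geom_default, spec, 0),
                   focal_roi(geom_default, spec))
  expect_error(matched_roi(geom_default, spec, 6), "5 mm")
})

test_that("bulk shift recovers rigid axial offsets and is antisymmetric", {
  tm <- visr_timing()
  ph <- small_phantom(seed = 17)
  ph2 <- ph
  ph2$scatterers$axial_mm <- ph$scatterers$axial_mm - 1.0
  ea <- envelope_image(small_rf(ph, snr_db = Inf, seed = 1))
  eb <- envelope_image(small_rf(ph2, snr_db = Inf, seed = 1))
  expect_equal(as.numeric(bulk_shift(ea, ea)), 0, tolerance = 1e-9)
  s <- bulk_shift(ea, eb)
  expect_equal(as.numeric(s), 1.0, tolerance = 0.05)
  expect_true(attr(s, "reliable"))
  expect_equal(as.numeric(bulk_shift(eb, ea)), -as.numeric(s),
               tolerance = 0.02)
})

test_that("ROI reduction matches a sort-based median and resists outliers", {
  vals <- matrix(runif(100, 1, 2), 10, 10)
  maps <- fake_maps(vals, axial_mm = seq(19, 21, length.out = 10),
                    lateral_mm = seq(-1, 1, length.out = 10))
  mask <- matrix(TRUE, 10, 10)
  red <- roi_reduce(maps, mask)
  expect_equal(red$pd_med, sort(as.vector(vals))[c(50, 51)] |> mean())
  expect_equal(red$n_valid, 100)
  expect_false(red$flagged)
  vals2 <- vals
  vals2[3, 7] <- 100 * vals2[3, 7]
  red2 <- roi_reduce(fake_maps(vals2, maps$axial_mm, maps$lateral_mm), mask)
  expect_lt(abs(red2$pd_med - red$pd_med), 0.05)
  # uniform map reduces to its value
  redu <- roi_reduce(fake_maps(matrix(3, 10, 10), maps$axial_mm,
                               maps$lateral_mm), mask)
  expect_equal(redu$re_med, 3)
  expect_error(roi_reduce(maps, mask & FALSE), "empty")
})

test_that("low validity flags the acquisition", {
  vals <- matrix(NA_real_, 10, 10)
  vals[1:2, 1] <- 1
  maps <- fake_maps(vals, seq(19, 21, length.out = 10),
                    seq(-1, 1, length.out = 10))
  red <- roi_reduce(maps, matrix(TRUE, 10, 10))
  expect_true(red$flagged)
})

test_that("adaptive ROI tracks tissue across compression better than the fixed ROI", {
  tm <- visr_timing()
  mech <- dplyr::bind_rows(
    mech_layer(0.03, 0.03, 0.012, 0.012, stiffening_per_mm = 0.03,
               z_top_mm = -Inf, z_bot_mm = 21.5),
    mech_layer(0.09, 0.09, 0.036, 0.036, stiffening_per_mm = 0.03,
               z_top_mm = 21.5, z_bot_mm = Inf))
  ph0 <- tissue_phantom(mech, seed = 21)
  rf0 <- synthesize_rf(ph0, tm, snr_db = 20, seed = 31)
  m0 <- visr_image(ncc_track(rf0))
  rf2 <- synthesize_rf(apply_compression(ph0, 2), tm, snr_db = 20, seed = 32)
  m2 <- visr_image(ncc_track(rf2))
  shift <- as.numeric(bulk_shift(envelope_image(rf0), envelope_image(rf2)))
  spec <- roi_spec()
  fixed0 <- roi_reduce(m0, focal_roi(m0, spec))$re_med
  fixed2 <- roi_reduce(m2, focal_roi(m2, spec))$re_med
  adapt0 <- roi_reduce(m0, matched_roi(m0, spec, 0))$re_med
  adapt2 <- roi_reduce(m2, matched_roi(m2, spec, shift))$re_med
  d_fixed <- abs(fixed2 - fixed0) / fixed0
  d_adapt <- abs(adapt2 - adapt0) / adapt0
  # the soft layer crosses the fixed ROI under compression: the fixed ROI
  # swaps tissue while the matched ROI keeps following the same layer
  expect_lt(d_adapt, d_fixed)
  expect_gt(d_fixed, 0.3)
  expect_lt(d_adapt, 0.25)
})
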