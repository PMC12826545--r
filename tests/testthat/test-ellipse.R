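protocol_angles <- c(0, 30, 60, 90)

ellipse_values <- function(a, b, phi, angles = protocol_angles) {
  tibble::tibble(angle_deg = angles,
                 value = visrcomp:::polar_ellipse_r(angles, a, b, phi))
}

test_that("noise-free elliptical data are inverted exactly", {
  f <- fit_ellipse(ellipse_values(4, 2, 30))
  expect_equal(f$a, 4, tolerance = 1e-3)
  expect_equal(f$b, 2, tolerance = 1e-3)
  expect_equal(f$phi_deg, 30, tolerance = 0.1)
  expect_equal(f$doa, 2, tolerance = 1e-3)
  expect_equal(f$r2, 1, tolerance = 1e-6)
  expect_false(f$out_of_protocol)
})

test_that("equal values fit a degenerate circle", {
  f <- fit_ellipse(tibble::tibble(angle_deg = protocol_angles,
                                  value = rep(5, 4)))
  expect_equal(f$a, 5, tolerance = 1e-4)
  expect_equal(f$doa, 1, tolerance = 1e-4)
  expect_true(is.na(f$r2))      # SS_tot = 0: R-squared undefined
  expect_equal(f$phi_deg, 0)    # tie-break convention
})

test_that("DoA is invariant to global scaling and phi honors a >= b", {
  df <- ellipse_values(3, 1.2, 140)
  f1 <- fit_ellipse(df)
  f2 <- fit_ellipse(dplyr::mutate(df, value = value * 7.3))
  expect_equal(f1$doa, f2$doa, tolerance = 1e-6)
  expect_gte(f1$a, f1$b)
  expect_true(f1$phi_deg >= 0 && f1$phi_deg < 180)
  expect_equal(f1$phi_deg, 140, tolerance = 0.1)
})

test_that("noisy ellipse data recover DoA within 10% (Monte Carlo)", {
  set.seed(77)
  doas <- vapply(seq_len(300), function(i) {
    df <- ellipse_values(3, 1, 0)
    df$value <- df$value * exp(rnorm(4, 0, 0.05))
    fit_ellipse(df)$doa
  }, numeric(1))
  expect_lt(abs(median(doas) - 3) / 3, 0.10)
})

test_that("R-squared decreases as noise increases", {
  set.seed(5)
  med_r2 <- vapply(c(0.01, 0.05, 0.15), function(s) {
    median(vapply(seq_len(60), function(i) {
      df <- ellipse_values(3, 1.5, 20)
      df$value <- df$value * exp(rnorm(4, 0, s))
      fit_ellipse(df)$r2
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_r2) < 0))
})

test_that("invalid inputs are rejected and off-protocol angles flagged", {
  expect_error(fit_ellipse(tibble::tibble(angle_deg = protocol_angles,
                                          value = c(1, 2, -1, 3))),
               "positive")
  f <- fit_ellipse(ellipse_values(2, 1, 10, angles = c(0, 45, 90, 135)))
  expect_true(f$out_of_protocol)
})

test_that("doa_table reduces a cohort scalar table and flags missing groups", {
  scal <- tidyr::expand_grid(subject_id = c("A", "B"),
                             metric = c("re", "rv"),
                             compression_mm = c(0, 2),
                             angle_deg = protocol_angles)
  scal$value <- visrcomp:::polar_ellipse_r(scal$angle_deg, 4, 2, 60)
  scal$value[scal$subject_id == "B" & scal$metric == "rv" &
               scal$compression_mm == 2 & scal$angle_deg == 0] <- NA
  out <- doa_table(scal)
  expect_equal(nrow(out), 8)
  good <- dplyr::filter(out, !missing)
  expect_equal(nrow(good), 7)
  expect_true(all(abs(good$doa - 2) < 1e-3))
  expect_true(out$missing[out$subject_id == "B" & out$metric == "rv" &
                            out$compression_mm == 2])
})
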