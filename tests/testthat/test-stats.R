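test_that("compression converts to the nominal strains of the protocol", {
  expect_equal(strain_from_compression(0, 20), 0)
  expect_equal(strain_from_compression(2, 20), 10)
  expect_equal(strain_from_compression(5, 20), 25)
  expect_error(strain_from_compression(-1, 20), "non-negative")
})

test_that("percent change behaves and chains multiplicatively", {
  expect_equal(percent_change(10, 10), 0)
  expect_equal(percent_change(10, 12.5), 25)
  expect_error(percent_change(0, 5), "zero")
  set.seed(42)
  for (i in 1:50) {
    abc <- runif(3, 0.1, 10)
    lhs <- (1 + percent_change(abc[1], abc[2]) / 100) *
      (1 + percent_change(abc[2], abc[3]) / 100)
    rhs <- 1 + percent_change(abc[1], abc[3]) / 100
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("baseline normalization maps the zero-compression value to exactly 1", {
  df <- tibble::tibble(compression_mm = c(0, 2, 5), value = c(4, 5, 6))
  out <- normalize_by_baseline(df)
  expect_identical(out$norm_value, c(1, 1.25, 1.5))
  allsame <- normalize_by_baseline(
    tibble::tibble(compression_mm = c(0, 2, 5), value = c(3, 3, 3)))
  expect_identical(allsame$norm_value, c(1, 1, 1))
  # grouped: every subject's baseline maps to 1; scale invariance
  g <- tidyr::expand_grid(subject = c("a", "b"), compression_mm = c(0, 2, 5))
  g$value <- runif(6, 1, 2)
  out_g <- normalize_by_baseline(dplyr::group_by(g, subject))
  expect_true(all(out_g$norm_value[out_g$compression_mm == 0] == 1))
  g2 <- dplyr::mutate(g, value = value * 13)
  expect_equal(normalize_by_baseline(dplyr::group_by(g2, subject))$norm_value,
               out_g$norm_value, tolerance = 1e-12)
  expect_error(normalize_by_baseline(
    tibble::tibble(compression_mm = c(2, 5), value = c(1, 2))), "baseline")
})

test_that("extreme angles follow argmin/argmax with smallest-angle ties", {
  df <- tibble::tibble(angle_deg = c(0, 30, 60, 90), value = c(3, 2, 4, 5))
  out <- extreme_angle_values(df)
  expect_equal(out$min_angle, 30)
  expect_equal(out$max_angle, 90)
  tie <- extreme_angle_values(
    tibble::tibble(angle_deg = c(0, 30, 60, 90), value = rep(2, 4)))
  expect_equal(tie$min_angle, 0)
  expect_equal(tie$max_angle, 0)
  set.seed(3)
  for (i in 1:25) { # brute-force scan oracle
    v <- runif(4)
    out <- extreme_angle_values(
      tibble::tibble(angle_deg = c(0, 30, 60, 90), value = v))
    expect_equal(out$min_value, min(v))
    expect_equal(out$max_value, max(v))
    expect_equal(out$min_angle, c(0, 30, 60, 90)[which.min(v)])
  }
  expect_error(extreme_angle_values(
    tibble::tibble(angle_deg = c(0, 30), value = c(1, 2))), "four")
})

test_that("Kruskal-Wallis reproduces the closed-form rank computation", {
  r <- kw_test(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(r$statistic, 7.2, tolerance = 1e-12)
  expect_equal(r$df, 2)
  same <- kw_test(list(c(1, 2, 3), c(3, 1, 2)))
  expect_lt(same$statistic, 1e-9)
  expect_gt(same$p, 0.99)
  expect_error(kw_test(list(1:3)), "2 non-empty")
})

test_that("rank-sum test gives the exact enumeration for small samples", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  expect_true(r$exact)
  same <- rank_sum_test(c(1, 2, 3), c(2, 1, 3) + 1e-9)
  expect_gt(same$p, 0.6)
  expect_error(rank_sum_test(numeric(0), 1:3), "empty")
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(8)
  g <- list(rnorm(12), rnorm(12, 0.5), rnorm(12, 1))
  h1 <- kw_test(g)
  h2 <- kw_test(lapply(g, function(x) exp(3 * x)))
  expect_equal(h1$statistic, h2$statistic, tolerance = 1e-12)
  expect_equal(h1$p, h2$p, tolerance = 1e-12)
  x <- rnorm(15); y <- rnorm(15, 0.8)
  expect_equal(rank_sum_test(x, y)$p,
               rank_sum_test(atan(x), atan(y))$p, tolerance = 1e-12)
})

test_that("H is non-negative and zero for fully tied data", {
  expect_gte(kw_test(list(rnorm(5), rnorm(5)))$statistic, 0)
  tied <- kw_test(list(rep(1, 4), rep(1, 4), rep(1, 4)))
  expect_true(!is.finite(tied$statistic) || tied$statistic <= 1e-9 ||
                is.na(tied$p))
})

test_that("Bonferroni threshold matches the printed multiple-comparison level", {
  a <- bonferroni_alpha(0.05, 12, 20)
  expect_equal(a, 0.05 / 240, tolerance = 1e-12)
  expect_equal(signif(a, 3), 2.08e-4)
  expect_equal(bonferroni_alpha(0.05, 1, 1), 0.05)
  expect_equal(bonferroni_alpha(0.06, 3, 2), 0.01)
  expect_error(bonferroni_alpha(0.05, 0, 20), "positive")
})
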