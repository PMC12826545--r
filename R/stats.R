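#' Convert surface compression to nominal strain
#'
#' Assuming uniformly distributed stress, an axial compression of `d` mm
#' relative to a focal depth `F` mm corresponds to `100 d / F` percent
#' strain: the protocol's 0, 2 and 5 mm at a 20-mm focus give 0%, 10% and
#' 25%.
#'
#' @param compression_mm Compression (>= 0), mm.
#' @param focal_depth_mm Focal depth (> 0), mm.
#' @return Percent strain.
#' @export
strain_from_compression <- function(compression_mm, focal_depth_mm = 20) {
  stopifnot_positive(focal_depth_mm, "focal_depth_mm")
  if (any(compression_mm < 0)) {
    stop("`compression_mm` must be non-negative", call. = FALSE)
  }
  100 * compression_mm / focal_depth_mm
}

#' Percent change between two values
#'
#' `100 (v_to - v_from) / v_from`.  Percent changes chain multiplicatively:
#' `(1 + pc(a,b)/100) (1 + pc(b,c)/100) = 1 + pc(a,c)/100`.
#'
#' @param v_from Baseline value (non-zero).
#' @param v_to Comparison value.
#' @return Percent change.
#' @export
percent_change <- function(v_from, v_to) {
  if (any(v_from == 0, na.rm = TRUE)) {
    stop("zero baseline in percent change", call. = FALSE)
  }
  100 * (v_to - v_from) / v_from
}

#' The protocol compression pairs
#'
#' @return A tibble with `from_mm`, `to_mm` and `label` for the 0-2, 2-5 and
#'   0-5 mm contrasts.
#' @export
compression_pairs <- function() {
  tibble::tibble(from_mm = c(0, 2, 0), to_mm = c(2, 5, 5),
                 label = c("0-2", "2-5", "0-5"))
}

#' Normalize per-compression values by the zero-compression baseline
#'
#' @param df A tibble containing `compression_mm` and `value` (plus any
#'   grouping columns already applied via [dplyr::group_by()], e.g. subject
#'   and metric).
#' @return `df` with a `norm_value` column; the 0-mm row maps to exactly 1.
#' @export
normalize_by_baseline <- function(df) {
  stopifnot(all(c("compression_mm", "value") %in% names(df)))
  fn <- function(d, ...) {
    base <- d$value[d$compression_mm == 0]
    if (length(base) != 1 || is.na(base) || base <= 0) {
      stop("missing or non-positive zero-compression baseline", call. = FALSE)
    }
    d$norm_value <- d$value / base
    d
  }
  if (dplyr::is_grouped_df(df)) {
    dplyr::ungroup(dplyr::group_modify(df, fn))
  } else {
    fn(df)
  }
}

#' Angles of extreme metric values
#'
#' Finds the imaging angles at which a metric is minimized ("minimum
#' angle") and maximized ("maximum angle") across the four protocol angles.
#' Ties are broken toward the smallest angle.
#'
#' @param df A tibble with `angle_deg` and `value` for the four protocol
#'   angles.
#' @return A one-row tibble: `min_angle`, `min_value`, `max_angle`,
#'   `max_value`.
#' @export
extreme_angle_values <- function(df) {
  stopifnot(all(c("angle_deg", "value") %in% names(df)))
  if (nrow(df) != 4 || any(is.na(df$value))) {
    stop("all four protocol angles must be present", call. = FALSE)
  }
  df <- df[order(df$angle_deg), ]
  i_min <- which.min(df$value) # which.min/max break ties toward first = smallest angle
  i_max <- which.max(df$value)
  tibble::tibble(min_angle = df$angle_deg[i_min], min_value = df$value[i_min],
                 max_angle = df$angle_deg[i_max], max_value = df$value[i_max])
}

#' Kruskal-Wallis test across compression levels
#'
#' Tie-corrected Kruskal-Wallis H statistic with a chi-squared
#' approximation on `k - 1` degrees of freedom (via [stats::kruskal.test()]),
#' packaged as a tidy one-row result.  Used for within-patient comparisons
#' of PD/RE/RV pixel distributions between the three compression levels.
#'
#' @param groups A list of numeric samples (>= 2 non-empty groups).
#' @param alpha Significance threshold to report alongside (e.g. the
#'   Bonferroni-adjusted level).
#' @return A tibble: `statistic` (H), `df`, `p`, `n_per_group`, `alpha`,
#'   `reject`.
#' @export
kw_test <- function(groups, alpha = 0.05) {
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) {
    stop("need at least 2 non-empty groups", call. = FALSE)
  }
  ht <- stats::kruskal.test(groups)
  tibble::tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value,
                 n_per_group = list(lengths(groups)), alpha = alpha,
                 reject = ht$p.value < alpha)
}

#' Wilcoxon rank-sum test between two groups
#'
#' Two-sided rank-sum test (via [stats::wilcox.test()]): exact enumeration
#' when both samples have at most `exact_max` observations and no ties,
#' otherwise the tie-corrected, continuity-corrected normal approximation.
#' Used for dense vs non-dense group comparisons and between-compression
#' contrasts of per-subject summaries.
#'
#' @param x,y Numeric samples (non-empty).
#' @param alpha Significance threshold to report alongside.
#' @param exact_max Largest per-group n for exact enumeration.
#' @return A tibble: `statistic` (rank-sum W of `x`), `p`, `n_per_group`,
#'   `alpha`, `reject`, `exact`.
#' @export
rank_sum_test <- function(x, y, alpha = 0.05, exact_max = 10) {
  if (length(x) == 0 || length(y) == 0) {
    stop("empty sample", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= exact_max && length(y) <= exact_max && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  tibble::tibble(statistic = unname(ht$statistic), p = ht$p.value,
                 n_per_group = list(c(length(x), length(y))), alpha = alpha,
                 reject = ht$p.value < alpha, exact = exact)
}

#' Bonferroni-adjusted significance threshold
#'
#' `base_alpha / (tests_per_patient * n_patients)`; with 12 tests per
#' patient (3 metrics x 4 angles) and 20 patients at base 0.05 this is
#' 2.08e-4.
#'
#' @param base_alpha Unadjusted level.
#' @param tests_per_patient Tests per patient (default 12).
#' @param n_patients Number of patients.
#' @return Adjusted alpha.
#' @export
bonferroni_alpha <- function(base_alpha = 0.05, tests_per_patient = 12,
                             n_patients = 20) {
  stopifnot_positive(base_alpha, "base_alpha")
  stopifnot_positive(tests_per_patient, "tests_per_patient")
  stopifnot_positive(n_patients, "n_patients")
  base_alpha / (tests_per_patient * n_patients)
}
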