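#' Study-level configuration
#'
#' Bundles the cohort, tracking, ROI and statistics settings for an
#' end-to-end synthetic study run, or loads them from a YAML file.
#'
#' @param n_dense,n_nondense Cohort composition.
#' @param seed Master seed: every random draw in the study derives from it.
#' @param cohort A [cohort_config()].
#' @param tracking A [tracking_params()].
#' @param roi A [roi_spec()].
#' @param base_alpha Unadjusted significance level.
#' @param engine Per-pixel fitting engine (see [visr_image()]).
#' @param keep_pixels Retain per-pixel focal-ROI values (needed for the
#'   per-patient Kruskal-Wallis grid).
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_dense = 10, n_nondense = 10, seed = 1L,
                         cohort = cohort_config(),
                         tracking = tracking_params(), roi = roi_spec(),
                         base_alpha = 0.05, engine = "grid",
                         keep_pixels = TRUE) {
  structure(list(n_dense = n_dense, n_nondense = n_nondense,
                 seed = as.integer(seed), cohort = cohort,
                 tracking = tracking, roi = roi, base_alpha = base_alpha,
                 engine = engine, keep_pixels = keep_pixels),
            class = "study_config")
}

#' @rdname study_config
#' @param path Path to a YAML file; recognized top-level blocks `study`,
#'   `cohort`, `tracking`, `roi` override the corresponding constructor
#'   arguments.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y$study %||% list()
  if (!is.null(y$cohort)) args$cohort <- do.call(cohort_config, y$cohort)
  if (!is.null(y$tracking)) args$tracking <- do.call(tracking_params, y$tracking)
  if (!is.null(y$roi)) args$roi <- do.call(roi_spec, y$roi)
  do.call(study_config, args)
}

process_acquisition <- function(subject, compression_mm, angle_deg, config) {
  rf <- acquire_rf(subject, compression_mm, angle_deg, config$cohort)
  disp <- ncc_track(rf, config$tracking)
  maps <- visr_image(disp, engine = config$engine)
  list(maps = maps, env = envelope_image(rf))
}

scalar_rows <- function(maps, mask, roi_mode, subject, compression_mm,
                        angle_deg, shift_mm, spec) {
  red <- roi_reduce(maps, mask, spec$min_valid_frac)
  tibble::tibble(
    subject_id = subject$subject_id, dense = subject$dense,
    compression_mm = compression_mm, angle_deg = angle_deg,
    roi_mode = roi_mode,
    metric = c("pd", "re", "rv"),
    value = c(red$pd_med, red$re_med, red$rv_med),
    n_valid = red$n_valid, flagged = red$flagged, shift_mm = shift_mm)
}

pixel_rows <- function(maps, mask, subject, compression_mm, angle_deg) {
  sel <- mask & maps$valid
  if (!any(sel)) return(NULL)
  tibble::tibble(
    subject_id = subject$subject_id, compression_mm = compression_mm,
    angle_deg = angle_deg,
    metric = rep(c("pd", "re", "rv"), each = sum(sel)),
    value = c(maps$pd[sel], maps$re[sel], maps$rv[sel]))
}

#' Run an end-to-end synthetic VisR compression study
#'
#' Generates the cohort, then for every subject, compression level and
#' imaging angle: synthesizes the RF ensemble, tracks displacement, fits
#' the per-pixel mass-spring-damper model, and reduces the maps over both
#' ROI policies (fixed focal ROI; feature-matched adaptive ROI via the bulk
#' shift against the same subject/angle at zero compression).  The
#' per-acquisition scalars then feed the anisotropy and statistics layers.
#'
#' Reruns with the same configuration and seed are bit-identical at the
#' scalar-table level.
#'
#' @param config A [study_config()].
#' @param progress Print per-subject progress lines.
#' @return An object of class `visr_study`: a list of tibbles — `cohort`
#'   (with ground truth), `scalars`, `pixels`, `doa`, `doa_change`,
#'   `normalized`, `pct_change` (all-angle, minimum-angle and
#'   maximum-angle percent changes), `group_tests`, `kw_grid` — plus a
#'   `provenance` record (seed, config hash, package version).
#' @export
run_study <- function(config = study_config(), progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  cohort <- make_cohort(config$n_dense, config$n_nondense, config$cohort,
                        config$seed)
  spec <- config$roi
  scalars <- list()
  pixels <- list()
  for (i in seq_len(nrow(cohort))) {
    subject <- cohort[i, ]
    if (progress) {
      message(sprintf("subject %s (%s)", subject$subject_id,
                      if (subject$dense) "dense" else "non-dense"))
    }
    for (angle in config$cohort$angles_deg) {
      env0 <- NULL
      for (cmm in config$cohort$compressions_mm) {
        acq <- process_acquisition(subject, cmm, angle, config)
        if (cmm == 0) env0 <- acq$env
        shift <- if (cmm == 0 || is.null(env0)) 0 else
          as.numeric(bulk_shift(env0, acq$env))
        f_mask <- focal_roi(acq$maps, spec)
        m_mask <- matched_roi(acq$maps, spec,
                              max(-5, min(5, shift)))
        scalars[[length(scalars) + 1L]] <- dplyr::bind_rows(
          scalar_rows(acq$maps, f_mask, "focal", subject, cmm, angle,
                      shift, spec),
          scalar_rows(acq$maps, m_mask, "adaptive", subject, cmm, angle,
                      shift, spec))
        if (config$keep_pixels) {
          pixels[[length(pixels) + 1L]] <-
            pixel_rows(acq$maps, f_mask, subject, cmm, angle)
        }
      }
    }
  }
  scalars <- dplyr::bind_rows(scalars)
  pixels <- dplyr::bind_rows(pixels)
  results <- study_tables(scalars, pixels, cohort, config)
  structure(c(list(cohort = cohort,
                   ground_truth = cohort_ground_truth(cohort, config$cohort),
                   scalars = scalars, pixels = pixels), results,
    list(provenance = list(
      seed = config$seed, config_hash = rlang::hash(unclass(config)),
      package_version = as.character(utils::packageVersion("visrcomp"))))),
    class = "visr_study")
}

# assemble the anisotropy / statistics result tables from the scalar table
study_tables <- function(scalars, pixels, cohort, config) {
  focal <- dplyr::filter(scalars, .data$roi_mode == "focal")
  pairs <- compression_pairs()
  alpha <- config$base_alpha
  n_patients <- max(1L, nrow(cohort))
  kw_alpha <- bonferroni_alpha(alpha, 12, n_patients)

  doa_tbl <- if (nrow(focal)) {
    doa_table(focal) |>
      dplyr::left_join(cohort[, c("subject_id", "dense")], by = "subject_id")
  } else tibble::tibble()

  pct_of <- function(df, value_col) {
    # df: subject_id, dense, metric, compression_mm, value
    purrr::pmap_dfr(pairs, function(from_mm, to_mm, label) {
      dplyr::inner_join(
        dplyr::filter(df, .data$compression_mm == from_mm),
        dplyr::filter(df, .data$compression_mm == to_mm),
        by = c("subject_id", "dense", "metric"), suffix = c("_from", "_to")
      ) |>
        dplyr::transmute(
          .data$subject_id, .data$dense, .data$metric, pair = label,
          pct_change = percent_change(
            .data[[paste0(value_col, "_from")]],
            .data[[paste0(value_col, "_to")]]))
    })
  }

  doa_change <- if (nrow(doa_tbl)) {
    pct_of(dplyr::transmute(doa_tbl, .data$subject_id, .data$dense,
                            .data$metric, .data$compression_mm,
                            value = .data$doa), "value")
  } else tibble::tibble()

  angle_avg <- focal |>
    dplyr::group_by(.data$subject_id, .data$dense, .data$metric,
                    .data$compression_mm) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")

  normalized <- if (nrow(angle_avg)) {
    angle_avg |>
      dplyr::group_by(.data$subject_id, .data$dense, .data$metric) |>
      normalize_by_baseline()
  } else tibble::tibble()

  pct_all <- if (nrow(angle_avg)) pct_of(angle_avg, "value") else
    tibble::tibble()

  # extreme angles chosen from the zero-compression per-angle values
  extremes <- focal |>
    dplyr::filter(.data$compression_mm == 0) |>
    dplyr::group_by(.data$subject_id, .data$dense, .data$metric) |>
    dplyr::group_modify(~ extreme_angle_values(.x)) |>
    dplyr::ungroup()

  pct_at_angle <- function(which_angle) {
    if (!nrow(extremes)) return(tibble::tibble())
    sel <- dplyr::inner_join(
      focal, extremes[, c("subject_id", "dense", "metric", which_angle)],
      by = c("subject_id", "dense", "metric")) |>
      dplyr::filter(.data$angle_deg == .data[[which_angle]]) |>
      dplyr::select("subject_id", "dense", "metric", "compression_mm",
                    "value")
    pct_of(sel, "value")
  }
  pct_change <- dplyr::bind_rows(
    dplyr::mutate(pct_all, angles = "all"),
    dplyr::mutate(pct_at_angle("min_angle"), angles = "min"),
    dplyr::mutate(pct_at_angle("max_angle"), angles = "max"))

  # dense vs non-dense rank-sum comparisons on each summary table
  group_test <- function(df, value_col, by_cols, table_name) {
    if (!nrow(df)) return(tibble::tibble())
    df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by_cols))) |>
      dplyr::group_modify(function(d, key) {
        x <- d[[value_col]][d$dense]
        y <- d[[value_col]][!d$dense]
        x <- x[!is.na(x)]
        y <- y[!is.na(y)]
        if (length(x) == 0 || length(y) == 0) {
          return(tibble::tibble(statistic = NA_real_, p = NA_real_,
                                n_dense = length(x), n_nondense = length(y),
                                reject = NA))
        }
        r <- rank_sum_test(x, y, alpha)
        tibble::tibble(statistic = r$statistic, p = r$p,
                       n_dense = length(x), n_nondense = length(y),
                       reject = r$reject)
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(table = table_name, .before = 1)
  }
  group_tests <- dplyr::bind_rows(
    group_test(doa_tbl, "doa", c("metric", "compression_mm"), "doa"),
    group_test(doa_change, "pct_change", c("metric", "pair"), "doa_change"),
    group_test(dplyr::filter(normalized, .data$compression_mm != 0),
               "norm_value", c("metric", "compression_mm"), "normalized"),
    group_test(pct_change, "pct_change", c("metric", "pair", "angles"),
               "pct_change"))

  # Kruskal-Wallis across compression levels per patient, metric and angle,
  # on the focal-ROI pixel distributions, at the Bonferroni-adjusted alpha
  kw_grid <- if (nrow(pixels)) {
    pixels |>
      dplyr::group_by(.data$subject_id, .data$metric, .data$angle_deg) |>
      dplyr::group_modify(function(d, key) {
        groups <- split(d$value, d$compression_mm)
        if (length(groups) < 2) {
          return(tibble::tibble(statistic = NA_real_, p = NA_real_,
                                reject = NA, alpha = kw_alpha))
        }
        r <- kw_test(groups, kw_alpha)
        tibble::tibble(statistic = r$statistic, p = r$p, reject = r$reject,
                       alpha = kw_alpha)
      }) |>
      dplyr::ungroup()
  } else tibble::tibble()

  list(doa = doa_tbl, doa_change = doa_change, normalized = normalized,
       pct_change = pct_change, group_tests = group_tests, kw_grid = kw_grid)
}

#' @export
print.visr_study <- function(x, ...) {
  cat(sprintf("VisR synthetic study: %d subjects, %d scalar rows, seed %d\n",
              nrow(x$cohort), nrow(x$scalars), x$provenance$seed))
  if (nrow(x$kw_grid)) {
    cat(sprintf("  Kruskal-Wallis grid: %d cells, %.1f%% reject at alpha = %.3g\n",
                nrow(x$kw_grid), 100 * mean(x$kw_grid$reject, na.rm = TRUE),
                x$kw_grid$alpha[1]))
  }
  invisible(x)
}

#' Write the study result tables as CSV files
#'
#' @param study A `visr_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("scalars", "doa", "doa_change", "normalized", "pct_change",
               "group_tests", "kw_grid")) {
    df <- study[[nm]]
    if (is.data.frame(df) && nrow(df)) {
      df <- dplyr::mutate(df, dplyr::across(
        dplyr::where(is.list), ~ vapply(.x, paste, character(1), collapse = ";")))
      write.csv(df, file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
    }
  }
  jsonlite::write_json(study$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Parameter-recovery validation against ground truth
#'
#' Joins study estimates to the generator's ground truth and reports median
#' absolute relative errors for focal RE and RV, recovery of the
#' ground-truth degree of anisotropy (from the RE and RV ellipse fits), and
#' the fraction of subject-angle cells where peak displacement decreases
#' under 5 mm compression (expected when moduli stiffen).
#'
#' With `mode = "analytic"` the RF/tracking chain is bypassed: noise-free
#' analytic displacement curves are fit directly, which isolates the fitter
#' (errors should be at optimizer tolerance).
#'
#' @param study A `visr_study` (for `mode = "full"`); if `NULL`, the study
#'   is run from `config`.
#' @param config A [study_config()].
#' @param mode `"full"` or `"analytic"`.
#' @return A one-row tibble of recovery summaries.
#' @export
validate_recovery <- function(study = NULL, config = study_config(),
                              mode = c("full", "analytic")) {
  mode <- match.arg(mode)
  if (mode == "analytic") {
    cohort <- make_cohort(config$n_dense, config$n_nondense, config$cohort,
                          config$seed)
    if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
    gt <- cohort_ground_truth(cohort, config$cohort)
    tm <- config$cohort$timing
    est <- purrr::pmap_dfr(gt[, c("gt_re", "gt_rv")], function(gt_re, gt_rv) {
      f <- fit_msd(msd_curve(gt_re, gt_rv, tm), tm)
      tibble::tibble(re_med = f$re, rv_med = f$rv)
    })
    return(tibble::tibble(
      mode = "analytic",
      mare_re = median(abs(est$re_med - gt$gt_re) / gt$gt_re),
      mare_rv = median(abs(est$rv_med - gt$gt_rv) / gt$gt_rv),
      mare_doa = NA_real_, pd_ordering = NA_real_,
      n_acquisitions = nrow(gt)))
  }
  if (is.null(study)) study <- run_study(config)
  cohort <- study$cohort
  gt <- cohort_ground_truth(cohort, config$cohort)
  est <- study$scalars |>
    dplyr::filter(.data$roi_mode == "focal") |>
    tidyr::pivot_wider(id_cols = c("subject_id", "compression_mm",
                                   "angle_deg"),
                       names_from = "metric", values_from = "value") |>
    dplyr::inner_join(gt, by = c("subject_id", "compression_mm",
                                 "angle_deg"))
  doa_est <- study$doa |>
    dplyr::filter(.data$metric %in% c("re", "rv"), !.data$missing) |>
    dplyr::left_join(cohort[, c("subject_id", "doa")],
                     by = "subject_id", suffix = c("", "_gt"))
  pd_ord <- study$scalars |>
    dplyr::filter(.data$roi_mode == "focal", .data$metric == "pd",
                  .data$compression_mm %in% c(0, 5)) |>
    tidyr::pivot_wider(id_cols = c("subject_id", "angle_deg"),
                       names_from = "compression_mm",
                       values_from = "value", names_prefix = "c") |>
    dplyr::summarise(frac = mean(.data$c5 < .data$c0, na.rm = TRUE))
  tibble::tibble(
    mode = "full",
    mare_re = median(abs(est$re - est$gt_re) / est$gt_re, na.rm = TRUE),
    mare_rv = median(abs(est$rv - est$gt_rv) / est$gt_rv, na.rm = TRUE),
    mare_doa = median(abs(doa_est$doa - doa_est$doa_gt) / doa_est$doa_gt,
                      na.rm = TRUE),
    pd_ordering = pd_ord$frac, n_acquisitions = nrow(est))
}

#' Study participants table
#'
#' Reads the packaged participant characteristics table of the emulated
#' clinical protocol: BI-RADS density rating (A-B non-dense, C-D dense),
#' age and medical history for each of the 20 subjects.
#'
#' @param path CSV path; defaults to the packaged copy.
#' @return A tibble with a logical `dense` column derived from the density
#'   rating.
#' @export
read_participants <- function(path = system.file("extdata",
                                                 "participants.csv",
                                                 package = "visrcomp")) {
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  df$dense <- df$birads_density %in% c("C", "D")
  df
}
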