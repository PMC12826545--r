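#' Cohort generator configuration
#'
#' Distributions and acquisition settings for synthetic subjects.  Defaults
#' define the simulated study conditions: 40 lines over a 2-cm field of
#' view at a 20-mm focus, 3 compression levels x 4 imaging angles per
#' subject, 20 dB RF SNR, ground-truth degree of anisotropy drawn uniformly
#' in 1.5-3.5 (anisotropic mammary tissue), transverse relative viscosity
#' giving micrometre-scale peak displacements, recovery time constants of
#' 0.4-1.0 ms, and per-mm compression stiffening drawn higher for the dense
#' group (4-8%/mm) than the non-dense group (1-4%/mm).
#'
#' @param doa_range Uniform range of ground-truth DoA (>= 1; use
#'   `c(1, 1)` for an isotropic cohort).
#' @param rv_trans_range Uniform range of transverse relative viscosity
#'   (ms/µm per unit force).
#' @param tau_range_ms Uniform range of the recovery time constant `rv/re`.
#' @param stiffening_dense,stiffening_nondense Uniform ranges of fractional
#'   stiffening per mm compression for the two groups.
#' @param snr_db RF signal-to-noise ratio, dB.
#' @param compressions_mm,angles_deg Protocol acquisition grid.
#' @param timing A [visr_timing()].
#' @param fs_mhz,c_mps,window_mm,lat_sigma_mm RF sampling settings (see
#'   [synthesize_rf()]).
#' @param density_per_mm2,n_lines,fov_mm,focal_depth_mm Phantom geometry
#'   (see [tissue_phantom()]).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(doa_range = c(1.5, 3.5),
                          rv_trans_range = c(0.006, 0.010),
                          tau_range_ms = c(0.4, 1.0),
                          stiffening_dense = c(0.04, 0.08),
                          stiffening_nondense = c(0.01, 0.04),
                          snr_db = 20,
                          compressions_mm = c(0, 2, 5),
                          angles_deg = c(0, 30, 60, 90),
                          timing = visr_timing(), fs_mhz = 40,
                          c_mps = 1540, window_mm = c(15, 25),
                          lat_sigma_mm = 0.3, density_per_mm2 = 60,
                          n_lines = 40, fov_mm = 20, focal_depth_mm = 20) {
  stopifnot(doa_range[1] >= 1, diff(doa_range) >= 0,
            all(rv_trans_range > 0), all(tau_range_ms > 0))
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Draws per-subject mechanical ground truth from the configured
#' distributions: transverse moduli and recovery time constant, a shared
#' degree of anisotropy for elasticity and viscosity (longitudinal =
#' transverse x DoA), an axis-of-symmetry orientation uniform in
#' `[0, 180)` (unknown a priori in vivo), and group-dependent compression
#' stiffening.  Subjects are reproducible under the master seed;
#' per-subject and per-acquisition seeds are derived streams.
#'
#' RF ensembles are realized lazily with [acquire_rf()] (one acquisition at
#' a time) rather than materialized for all subjects at once;
#' [cohort_acquisitions()] enumerates the full protocol grid of
#' `3 compressions x 4 angles` per subject.
#'
#' @param n_dense,n_nondense Subject counts per density group (>= 0).
#' @param config A [cohort_config()].
#' @param seed Master seed.
#' @return A tibble with one row per subject: identifiers, group label,
#'   ground-truth moduli, `doa`, `aos_deg`, `stiffening_per_mm` and the
#'   derived `subject_seed`.
#' @export
make_cohort <- function(n_dense = 10, n_nondense = 10,
                        config = cohort_config(), seed = 1L) {
  stopifnot(n_dense >= 0, n_nondense >= 0)
  n <- n_dense + n_nondense
  if (n == 0) {
    return(tibble::tibble(subject_id = character(), dense = logical(),
                          doa = numeric(), aos_deg = numeric(),
                          re_long = numeric(), re_trans = numeric(),
                          rv_long = numeric(), rv_trans = numeric(),
                          tau_ms = numeric(), stiffening_per_mm = numeric(),
                          subject_seed = integer()))
  }
  dense <- rep(c(TRUE, FALSE), c(n_dense, n_nondense))
  with_seed_(seed, {
    doa <- runif(n, config$doa_range[1], config$doa_range[2])
    rv_trans <- runif(n, config$rv_trans_range[1], config$rv_trans_range[2])
    tau <- runif(n, config$tau_range_ms[1], config$tau_range_ms[2])
    aos <- runif(n, 0, 180)
    stiff <- ifelse(
      dense,
      runif(n, config$stiffening_dense[1], config$stiffening_dense[2]),
      runif(n, config$stiffening_nondense[1], config$stiffening_nondense[2]))
  })
  tibble::tibble(
    subject_id = sprintf("S%02d", seq_len(n)), dense = dense, doa = doa,
    aos_deg = aos, re_trans = rv_trans / tau,
    re_long = rv_trans / tau * doa, rv_trans = rv_trans,
    rv_long = rv_trans * doa, tau_ms = tau, stiffening_per_mm = stiff,
    subject_seed = vapply(seq_len(n), function(i) derive_seed(seed, i),
                          integer(1)))
}

#' @rdname make_cohort
#' @param cohort A cohort tibble from `make_cohort()`.
#' @return `cohort_acquisitions()`: one row per subject x compression x
#'   angle with the derived acquisition seed.
#' @export
cohort_acquisitions <- function(cohort, config = cohort_config()) {
  grid <- tidyr::expand_grid(
    subject_id = cohort$subject_id,
    compression_mm = config$compressions_mm,
    angle_deg = config$angles_deg)
  grid |>
    dplyr::left_join(cohort[, c("subject_id", "subject_seed")],
                     by = "subject_id") |>
    dplyr::mutate(acq_seed = purrr::pmap_int(
      list(.data$subject_seed, .data$compression_mm, .data$angle_deg),
      function(s, cmm, a) derive_seed(s, 100 + cmm, 200 + a))) |>
    dplyr::select(-"subject_seed")
}

subject_mech <- function(subject) {
  mech_layer(re_long = subject$re_long, re_trans = subject$re_trans,
             rv_long = subject$rv_long, rv_trans = subject$rv_trans,
             aos_deg = subject$aos_deg,
             stiffening_per_mm = subject$stiffening_per_mm,
             dense = subject$dense)
}

subject_phantom <- function(subject, config = cohort_config()) {
  tissue_phantom(subject_mech(subject), seed = subject$subject_seed,
                 density_per_mm2 = config$density_per_mm2,
                 n_lines = config$n_lines, fov_mm = config$fov_mm,
                 focal_depth_mm = config$focal_depth_mm)
}

#' Realize the RF ensemble of one acquisition
#'
#' Rebuilds the subject's phantom from its derived seed (the same scatterer
#' field across all 12 acquisitions of a subject), applies the compression,
#' and synthesizes the RF ensemble at the requested angle with a
#' per-acquisition noise seed.
#'
#' @param subject One row of a [make_cohort()] tibble.
#' @param compression_mm,angle_deg Acquisition labels.
#' @param config A [cohort_config()].
#' @return An `rf_ensemble`.
#' @export
acquire_rf <- function(subject, compression_mm, angle_deg,
                       config = cohort_config()) {
  stopifnot(nrow(subject) == 1)
  ph <- subject_phantom(subject, config)
  ph <- apply_compression(ph, compression_mm)
  synthesize_rf(ph, timing = config$timing, angle_deg = angle_deg,
                snr_db = config$snr_db,
                seed = derive_seed(subject$subject_seed, 100 + compression_mm,
                                   200 + angle_deg),
                fs_mhz = config$fs_mhz, c_mps = config$c_mps,
                window_mm = config$window_mm,
                lat_sigma_mm = config$lat_sigma_mm)
}

#' Ground-truth moduli on the acquisition grid
#'
#' Expected relative elasticity/viscosity at each compression and imaging
#' angle, from the angular modulus law and the per-mm stiffening, plus the
#' ground-truth DoA.
#'
#' @param cohort A [make_cohort()] tibble.
#' @param config A [cohort_config()].
#' @return A tibble: subject, compression, angle, `gt_re`, `gt_rv`,
#'   `gt_doa`.
#' @export
cohort_ground_truth <- function(cohort, config = cohort_config()) {
  tidyr::expand_grid(
    subject_id = cohort$subject_id,
    compression_mm = config$compressions_mm,
    angle_deg = config$angles_deg) |>
    dplyr::left_join(cohort, by = "subject_id") |>
    dplyr::mutate(
      gain = (1 + .data$stiffening_per_mm)^.data$compression_mm,
      gt_re = modulus_at_angle(.data$re_long, .data$re_trans, .data$aos_deg,
                               .data$angle_deg) * .data$gain,
      gt_rv = modulus_at_angle(.data$rv_long, .data$rv_trans, .data$aos_deg,
                               .data$angle_deg) * .data$gain,
      gt_doa = .data$doa) |>
    dplyr::select("subject_id", "dense", "compression_mm", "angle_deg",
                  "gt_re", "gt_rv", "gt_doa")
}
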