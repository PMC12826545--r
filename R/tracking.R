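#' Displacement tracking parameters
#'
#' Defaults follow the clinical processing chain: 376-µm kernel, 80-µm
#' search region, spline interpolation factor 4, with 75% kernel overlap
#' (axial pixel pitch about 94 µm) and a 0.8 peak-correlation validity
#' threshold.
#'
#' @param kernel_um Kernel length, µm.
#' @param search_um Search region, µm (estimates span `+/- search_um / 2`).
#' @param interp Correlation upsampling factor (>= 1).
#' @param overlap Kernel overlap fraction in `[0, 1)`.
#' @param min_corr Peak-correlation threshold below which an estimate is
#'   flagged invalid.
#' @return An object of class `tracking_params`.
#' @export
tracking_params <- function(kernel_um = 376, search_um = 80, interp = 4,
                            overlap = 0.75, min_corr = 0.8) {
  stopifnot_positive(kernel_um, "kernel_um")
  stopifnot_positive(search_um, "search_um")
  stopifnot(interp >= 1, overlap >= 0, overlap < 1)
  structure(list(kernel_um = kernel_um, search_um = search_um,
                 interp = as.integer(interp), overlap = overlap,
                 min_corr = min_corr), class = "tracking_params")
}

#' Track axial displacement through slow time by normalized cross-correlation
#'
#' For each axial kernel and slow-time event, displacement is estimated
#' relative to the mean of the reference events using zero-normalized
#' cross-correlation over the search region, with the correlation function
#' upsampled by the interpolation factor (natural cubic spline) and refined
#' by a parabolic vertex fit.  Kernels with zero signal variance are flagged
#' invalid (correlation 0, displacement `NA`).
#'
#' @param rf An `rf_ensemble` from [synthesize_rf()] or [read_rf()].
#' @param params A [tracking_params()] object.
#' @return An object of class `visr_disp` with micrometre displacement and
#'   peak-correlation arrays (axial pixel x slow-time event x lateral
#'   line), axial positions (kernel centres, mm from the transducer face),
#'   event times and the acquisition metadata.
#' @export
ncc_track <- function(rf, params = tracking_params()) {
  stopifnot(inherits(rf, "rf_ensemble"))
  dz_um <- rf$c_mps / (2 * rf$fs_mhz) # µm per sample (c m/s, fs MHz)
  kernel <- max(2L, as.integer(round(params$kernel_um / dz_um)))
  max_lag <- as.integer(ceiling((params$search_um / 2) / dz_um))
  step <- max(1L, as.integer(round(kernel * (1 - params$overlap))))
  res <- ncc_track_cpp(rf$samples, rf$timing$n_reference, kernel, max_lag,
                       params$interp, step)
  disp <- res$lag * dz_um
  # Re-zero each pixel on its own reference-event estimates: the tracked
  # position of the (motionless) reference events measures the pixel's
  # speckle-dependent peak-interpolation bias, which is removed from the
  # whole slow-time curve.
  n_ref <- rf$timing$n_reference
  base <- apply(disp[, seq_len(n_ref), , drop = FALSE], c(1, 3), mean)
  disp <- disp - aperm(array(base, dim(disp)[c(1, 3, 2)]), c(1, 3, 2))
  # clip to the configured search region
  half <- params$search_um / 2
  disp[disp > half] <- half
  disp[disp < -half] <- -half
  structure(list(
    disp_um = disp, corr = res$corr,
    axial_mm = rf$z0_mm + res$center_sample * dz_um / 1000,
    lateral_mm = rf$line_lat_mm, times_ms = event_times(rf$timing),
    timing = rf$timing, params = params,
    compression_mm = rf$compression_mm, angle_deg = rf$angle_deg,
    focal_depth_mm = rf$focal_depth_mm, ground_truth = rf$ground_truth
  ), class = "visr_disp")
}

#' Peak displacement of a slow-time displacement curve
#'
#' The maximum of the tracked displacement over slow time, signed toward the
#' push direction (away from the transducer).  Invalid estimates are
#' ignored; an all-invalid curve yields `NA`.
#'
#' @param curve Numeric displacement values (µm) through slow time, or a
#'   data frame with a `disp_um` column (e.g. from [msd_response()]).
#' @return Peak displacement, µm.
#' @export
peak_displacement <- function(curve) {
  if (is.data.frame(curve)) curve <- curve$disp_um
  if (length(curve) == 0) stop("empty displacement curve", call. = FALSE)
  if (all(is.na(curve))) return(NA_real_)
  max(curve, na.rm = TRUE)
}

#' @export
print.visr_disp <- function(x, ...) {
  d <- dim(x$disp_um)
  cat(sprintf(
    "Displacement field: %d axial pixels x %d events x %d lines (%.2f-%.2f mm)\n",
    d[1], d[2], d[3], min(x$axial_mm), max(x$axial_mm)))
  invisible(x)
}

#' Tidy a displacement field
#'
#' @param x A `visr_disp` object.
#' @param ... Unused.
#' @return A long tibble: `axial_mm`, `lateral_mm`, `time_ms`, `disp_um`,
#'   `corr`.
#' @export
tidy.visr_disp <- function(x, ...) {
  d <- dim(x$disp_um)
  tibble::tibble(
    axial_mm = rep(x$axial_mm, times = d[2] * d[3]),
    lateral_mm = rep(x$lateral_mm, each = d[1] * d[2]),
    time_ms = rep(rep(x$times_ms, each = d[1]), times = d[3]),
    disp_um = as.vector(x$disp_um),
    corr = as.vector(x$corr)
  )
}
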