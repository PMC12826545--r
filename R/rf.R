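#' Synthesize an RF speckle ensemble for one VisR acquisition
#'
#' Each A-line is the superposition of band-limited echoes (tracking-frequency
#' carrier with a Gaussian envelope, Gaussian lateral beam weighting) centred
#' at every scatterer's instantaneous axial position, sampled at `fs_mhz`,
#' plus seeded white noise at the configured signal-to-noise ratio.  The
#' displacement of each scatterer through slow time follows the
#' mass-spring-damper response of its mechanical layer, evaluated at the
#' layer's moduli for the acquisition angle (see [modulus_at_angle()]).
#' Identical seeds give bit-identical output.
#'
#' @param phantom A [tissue_phantom()], already compressed if applicable
#'   (see [apply_compression()]).
#' @param timing A [visr_timing()].
#' @param angle_deg Imaging angle (protocol angles: 0, 30, 60, 90).
#' @param snr_db Signal-to-noise ratio in dB (`Inf` for noise-free).
#' @param seed Integer seed for the noise realization.
#' @param fs_mhz RF sampling frequency, MHz (must be at least 4x the
#'   tracking frequency).
#' @param c_mps Speed of sound, m/s.
#' @param window_mm Imaged depth window `c(z0, z1)`, mm.
#' @param lat_sigma_mm Lateral beam Gaussian sigma, mm.
#' @param disp_schedule Optional displacement override: a matrix of
#'   micrometre axial displacements, `n_layers x n_events` (or `1 x
#'   n_events` applied to all scatterers), replacing the mass-spring-damper
#'   schedule.  Used for rigid-motion calibration.
#' @return An object of class `rf_ensemble` with the sample array
#'   (fast time x slow time x lateral line) and full acquisition metadata.
#' @export
synthesize_rf <- function(phantom, timing = visr_timing(), angle_deg = 0,
                          snr_db = 20, seed = 1L, fs_mhz = 40,
                          c_mps = 1540, window_mm = c(15, 25),
                          lat_sigma_mm = 0.3, disp_schedule = NULL) {
  stopifnot(inherits(phantom, "tissue_phantom"))
  if (nrow(phantom$scatterers) == 0) stop("empty scatterer list", call. = FALSE)
  if (snr_db <= 0) stop("`snr_db` must be positive (use Inf for noise-free)", call. = FALSE)
  if (fs_mhz < 4 * timing$track_freq_mhz) {
    stop("`fs_mhz` must be at least 4x the tracking frequency", call. = FALSE)
  }
  ne <- n_events(timing)
  if (is.null(disp_schedule)) {
    mod <- layer_moduli_at_angle(phantom$mech, angle_deg)
    disp_schedule <- t(vapply(seq_len(nrow(mod)), function(i) {
      msd_curve(mod$re[i], mod$rv[i], timing)
    }, numeric(ne)))
  } else {
    disp_schedule <- matrix(disp_schedule, ncol = ne)
    if (nrow(disp_schedule) == 1 && nrow(phantom$mech) > 1) {
      disp_schedule <- disp_schedule[rep(1, nrow(phantom$mech)), , drop = FALSE]
    }
  }
  # 2-cycle Gaussian envelope: FWHM equal to the nominal pulse duration
  sigma_t_us <- (2 / timing$track_freq_mhz) / (2 * sqrt(2 * log(2)))
  c_mm_us <- c_mps / 1000
  n_samples <- floor((window_mm[2] - window_mm[1]) * 2 / c_mm_us * fs_mhz) + 1L
  sc <- phantom$scatterers
  # keep scatterers whose echoes can reach the window
  margin <- 3.5 * sigma_t_us * c_mm_us / 2 + 0.05
  keep <- sc$axial_mm > window_mm[1] - margin & sc$axial_mm < window_mm[2] + margin
  sc <- sc[keep, , drop = FALSE]
  samples <- rf_synth_cpp(sc$axial_mm, sc$lateral_mm, sc$amplitude,
                          sc$layer - 1L, disp_schedule, phantom$line_lat_mm,
                          fs_mhz, c_mps, window_mm[1], n_samples,
                          timing$track_freq_mhz, sigma_t_us, lat_sigma_mm,
                          3 * lat_sigma_mm)
  if (is.finite(snr_db)) {
    noise_sd <- sqrt(mean(samples^2)) / 10^(snr_db / 20)
    noise <- with_seed_(seed, rnorm(length(samples), sd = noise_sd))
    samples <- samples + noise
  }
  structure(list(
    samples = samples, fs_mhz = fs_mhz, c_mps = c_mps, timing = timing,
    z0_mm = window_mm[1], line_lat_mm = phantom$line_lat_mm,
    compression_mm = phantom$compression_mm, angle_deg = angle_deg,
    snr_db = snr_db, seed = as.integer(seed),
    focal_depth_mm = phantom$focal_depth_mm,
    ground_truth = phantom$mech
  ), class = "rf_ensemble")
}

#' Envelope image of one slow-time event
#'
#' Magnitude of the analytic signal (Hilbert transform via FFT) of each
#' A-line, as a fast-time x lateral matrix.  Used for feature matching
#' between compression levels.
#'
#' @param rf An `rf_ensemble`.
#' @param event Slow-time event index (default: first reference event).
#' @return A matrix (samples x lines) with `axial_mm` attribute.
#' @export
envelope_image <- function(rf, event = 1L) {
  stopifnot(inherits(rf, "rf_ensemble"))
  x <- rf$samples[, event, ]
  n <- nrow(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  env <- abs(stats::mvfft(stats::mvfft(as.matrix(x)) * h, inverse = TRUE) / n)
  attr(env, "axial_mm") <- rf$z0_mm +
    (seq_len(n) - 1) * rf$c_mps / 1000 / (2 * rf$fs_mhz)
  attr(env, "lateral_mm") <- rf$line_lat_mm
  env
}

#' Write / read an RF ensemble fixture
#'
#' The on-disk format is a little-endian float32 binary array (fast time x
#' slow time x lateral) at `<path>.f32` plus a JSON sidecar `<path>.json`
#' carrying sampling, timing, geometry, acquisition labels and the
#' ground-truth block for synthetic data.
#'
#' @param rf An `rf_ensemble`.
#' @param path Path prefix (without extension).
#' @return `write_rf()` returns `path` invisibly; `read_rf()` returns the
#'   reconstructed `rf_ensemble` (samples in float32 precision).
#' @export
write_rf <- function(rf, path) {
  stopifnot(inherits(rf, "rf_ensemble"))
  con <- file(paste0(path, ".f32"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rf$samples), con, size = 4L, endian = "little")
  meta <- list(
    dim = dim(rf$samples), fs_mhz = rf$fs_mhz, c_mps = rf$c_mps,
    timing = unclass(rf$timing), z0_mm = rf$z0_mm,
    line_lat_mm = rf$line_lat_mm, compression_mm = rf$compression_mm,
    angle_deg = rf$angle_deg, snr_db = rf$snr_db, seed = rf$seed,
    focal_depth_mm = rf$focal_depth_mm,
    ground_truth = as.list(rf$ground_truth)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_rf
#' @export
read_rf <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(paste0(path, ".f32"), "rb")
  on.exit(close(con))
  samples <- readBin(con, what = "numeric", n = n, size = 4L,
                     endian = "little")
  dim(samples) <- meta$dim
  structure(list(
    samples = samples, fs_mhz = meta$fs_mhz, c_mps = meta$c_mps,
    timing = do.call(visr_timing, meta$timing[c(
      "n_reference", "n_tracks_between", "n_tracks_after", "prf_khz",
      "push_cycles", "push_freq_mhz", "track_freq_mhz")]),
    z0_mm = meta$z0_mm, line_lat_mm = meta$line_lat_mm,
    compression_mm = meta$compression_mm, angle_deg = meta$angle_deg,
    snr_db = meta$snr_db %||% Inf, seed = meta$seed,
    focal_depth_mm = meta$focal_depth_mm,
    ground_truth = tibble::as_tibble(meta$ground_truth)
  ), class = "rf_ensemble")
}

#' @export
print.rf_ensemble <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf(
    "RF ensemble: %d samples x %d events x %d lines; fs %g MHz; %g mm compression, %g deg angle\n",
    d[1], d[2], d[3], x$fs_mhz, x$compression_mm, x$angle_deg))
  invisible(x)
}
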