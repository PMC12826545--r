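#' Region-of-interest specification
#'
#' The quantitative analysis uses values within 3 mm axially of the focal
#' depth and 3 mm laterally of the image centre.  The symmetric axial
#' reading is the default; `above_only = TRUE` restricts to tissue above the
#' focus.
#'
#' @param axial_halfwidth_mm,lateral_halfwidth_mm ROI half-extents, mm.
#' @param focal_depth_mm ARFI focal depth, mm.
#' @param above_only Use only the region above the focus axially.
#' @param min_valid_frac Minimum fraction of valid pixels for an
#'   acquisition-level reduction to be trusted.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(axial_halfwidth_mm = 3, lateral_halfwidth_mm = 3,
                     focal_depth_mm = 20, above_only = FALSE,
                     min_valid_frac = 0.25) {
  stopifnot_positive(axial_halfwidth_mm, "axial_halfwidth_mm")
  stopifnot_positive(lateral_halfwidth_mm, "lateral_halfwidth_mm")
  stopifnot_positive(focal_depth_mm, "focal_depth_mm")
  structure(list(axial_halfwidth_mm = axial_halfwidth_mm,
                 lateral_halfwidth_mm = lateral_halfwidth_mm,
                 focal_depth_mm = focal_depth_mm, above_only = above_only,
                 min_valid_frac = min_valid_frac), class = "roi_spec")
}

roi_mask_ <- function(axial_mm, lateral_mm, z_lo, z_hi, spec) {
  centre <- mean(range(lateral_mm))
  ax <- axial_mm >= z_lo & axial_mm <= z_hi
  lat <- abs(lateral_mm - centre) <= spec$lateral_halfwidth_mm
  outer(ax, lat, `&`)
}

#' Fixed focal region of interest
#'
#' Pixel mask that is true where the depth is within the axial half-width of
#' the focal depth and the lateral position within the lateral half-width of
#' the image centre.
#'
#' @param geometry A `visr_maps`/`visr_disp` object, or any list with
#'   `axial_mm` and `lateral_mm` vectors.
#' @param spec A [roi_spec()].
#' @return A logical matrix (axial x lateral).
#' @export
focal_roi <- function(geometry, spec = roi_spec()) {
  z_lo <- spec$focal_depth_mm - spec$axial_halfwidth_mm
  z_hi <- if (spec$above_only) spec$focal_depth_mm else
    spec$focal_depth_mm + spec$axial_halfwidth_mm
  m <- roi_mask_(geometry$axial_mm, geometry$lateral_mm, z_lo, z_hi, spec)
  if (!any(m)) {
    stop("focal ROI lies outside the imaged region", call. = FALSE)
  }
  m
}

#' Bulk axial shift between two envelope images
#'
#' The axial lag maximizing the mean per-column zero-normalized
#' cross-correlation between a reference and a comparison envelope image,
#' refined to subsample precision by a parabolic vertex fit.  A positive
#' shift means the features of the comparison image moved toward the
#' transducer (as under compression).
#'
#' @param env_ref,env_cmp Envelope images from [envelope_image()] sharing a
#'   geometry.
#' @param max_shift_mm Search extent, mm.
#' @return The shift in mm, with attributes `peak_corr` and `reliable`
#'   (peak correlation >= 0.5).
#' @export
bulk_shift <- function(env_ref, env_cmp, max_shift_mm = 5) {
  stopifnot(all(dim(env_ref) == dim(env_cmp)))
  z <- attr(env_ref, "axial_mm")
  dz <- z[2] - z[1]
  max_lag <- as.integer(floor(max_shift_mm / dz))
  ns <- nrow(env_ref)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(l) {
    # positive lag: cmp rows i match ref rows i + l
    i_cmp <- seq(max(1, 1 - l), min(ns, ns - l))
    i_ref <- i_cmp + l
    a <- env_cmp[i_cmp, , drop = FALSE]
    b <- env_ref[i_ref, , drop = FALSE]
    num <- colSums(a * b) - nrow(a) * colMeans(a) * colMeans(b)
    den <- sqrt((colSums(a^2) - nrow(a) * colMeans(a)^2) *
                  (colSums(b^2) - nrow(b) * colMeans(b)^2))
    mean(ifelse(den > 0, num / den, 0))
  }, numeric(1))
  i <- which.max(cc)
  lag <- lags[i]
  peak <- cc[i]
  if (i > 1 && i < length(cc)) {
    den <- cc[i - 1] - 2 * cc[i] + cc[i + 1]
    if (den < 0) {
      delta <- 0.5 * (cc[i - 1] - cc[i + 1]) / den
      lag <- lag + delta
      peak <- peak - 0.25 * (cc[i - 1] - cc[i + 1]) * delta
    }
  }
  structure(lag * dz, peak_corr = peak, reliable = peak >= 0.5)
}

#' Feature-matched (adaptive) region of interest
#'
#' Translates the focal ROI axially by the measured bulk shift so that it
#' follows the same tissue across compression levels, then crops it back to
#' within the axial half-width of the focal depth so forcing conditions stay
#' comparable.
#'
#' @param geometry As in [focal_roi()].
#' @param spec A [roi_spec()].
#' @param shift_mm Bulk shift from [bulk_shift()] (positive = features moved
#'   toward the transducer); must satisfy `|shift| <= 5` mm.
#' @return A logical matrix (axial x lateral).
#' @export
matched_roi <- function(geometry, spec = roi_spec(), shift_mm = 0) {
  if (abs(shift_mm) > 5) {
    stop("|shift_mm| must be at most 5 mm", call. = FALSE)
  }
  z_hi0 <- if (spec$above_only) spec$focal_depth_mm else
    spec$focal_depth_mm + spec$axial_halfwidth_mm
  z_lo0 <- spec$focal_depth_mm - spec$axial_halfwidth_mm
  # translate toward the transducer by the shift, then clip to the focal band
  z_lo <- max(z_lo0 - shift_mm, z_lo0)
  z_hi <- min(z_hi0 - shift_mm, z_hi0)
  if (z_lo >= z_hi) {
    stop("clipping emptied the matched ROI (degenerate ROI)", call. = FALSE)
  }
  m <- roi_mask_(geometry$axial_mm, geometry$lateral_mm, z_lo, z_hi, spec)
  if (!any(m)) {
    stop("matched ROI lies outside the imaged region", call. = FALSE)
  }
  m
}

#' Reduce VisR maps to per-acquisition scalars over an ROI
#'
#' Medians of the valid masked pixels for PD, RE and RV, with the valid
#' pixel count.  Acquisitions in which fewer than the configured fraction of
#' masked pixels are valid are flagged.
#'
#' @param maps A `visr_maps` object.
#' @param mask Logical pixel mask from [focal_roi()] or [matched_roi()].
#' @param min_valid_frac Minimum valid fraction before flagging.
#' @return A one-row tibble: `pd_med`, `re_med`, `rv_med`, `n_valid`,
#'   `n_mask`, `flagged`.
#' @export
roi_reduce <- function(maps, mask, min_valid_frac = 0.25) {
  stopifnot(inherits(maps, "visr_maps"), all(dim(mask) == dim(maps$pd)))
  if (!any(mask)) stop("empty ROI mask", call. = FALSE)
  sel <- mask & maps$valid
  n_valid <- sum(sel)
  flagged <- n_valid < min_valid_frac * sum(mask)
  med <- function(m) if (n_valid == 0) NA_real_ else median(m[sel])
  tibble::tibble(pd_med = med(maps$pd), re_med = med(maps$re),
                 rv_med = med(maps$rv), n_valid = n_valid,
                 n_mask = sum(mask), flagged = flagged)
}
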