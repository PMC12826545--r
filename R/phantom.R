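#' Angular variation of a modulus in a transversely isotropic material
#'
#' Moduli measured by rotating the imaging plane vary with a 180-degree
#' period between the longitudinal value (along the material axis of
#' symmetry, AoS) and the transverse value.  The variation is modelled as a
#' polar ellipse, `r(theta) = a b / sqrt(b^2 cos^2 D + a^2 sin^2 D)` with
#' `D = theta - aos`, which is more accurate than a sinusoid at high
#' anisotropy.
#'
#' @param m_long Modulus along the AoS (> 0).
#' @param m_trans Modulus transverse to the AoS (> 0).
#' @param aos_deg AoS orientation, degrees.
#' @param theta_deg Probe angle(s), degrees.
#' @return Modulus value(s) at `theta_deg`; equals `m_long` on axis and is
#'   bounded by the two moduli.
#' @examples
#' modulus_at_angle(4, 2, 0, 45) # 8 / sqrt(10)
#' @export
modulus_at_angle <- function(m_long, m_trans, aos_deg, theta_deg) {
  stopifnot_positive(m_long, "m_long")
  stopifnot_positive(m_trans, "m_trans")
  d <- (theta_deg - aos_deg) * pi / 180
  m_long * m_trans / sqrt(m_trans^2 * cos(d)^2 + m_long^2 * sin(d)^2)
}

#' Mechanical ground truth for a phantom layer
#'
#' One row per mechanical layer (use a single row for homogeneous tissue).
#' Layers are delimited by depth at zero compression; scatterers keep their
#' layer identity when the phantom is compressed.
#'
#' @param re_long,re_trans Relative elasticity along/transverse to the AoS
#'   (1/µm per unit force).
#' @param rv_long,rv_trans Relative viscosity along/transverse to the AoS
#'   (ms/µm per unit force).
#' @param aos_deg Axis-of-symmetry orientation in `[0, 180)` degrees
#'   (assumed parallel to the skin surface).
#' @param stiffening_per_mm Fractional modulus increase per mm of surface
#'   compression; may be negative (softening).
#' @param z_top_mm,z_bot_mm Layer depth extent at zero compression, mm.
#' @param dense Logical group label (dense-breast analogue).
#' @return A tibble with one row per layer and a `doa` column
#'   (`max/min` of the angular modulus profile, always >= 1).
#' @export
mech_layer <- function(re_long, re_trans, rv_long, rv_trans, aos_deg = 0,
                       stiffening_per_mm = 0, z_top_mm = -Inf,
                       z_bot_mm = Inf, dense = FALSE) {
  for (nm in c("re_long", "re_trans", "rv_long", "rv_trans")) {
    stopifnot_positive(get(nm), nm)
  }
  tibble::tibble(z_top_mm = z_top_mm, z_bot_mm = z_bot_mm,
                 re_long = re_long, re_trans = re_trans,
                 rv_long = rv_long, rv_trans = rv_trans,
                 aos_deg = aos_deg %% 180,
                 stiffening_per_mm = stiffening_per_mm,
                 dense = dense,
                 doa = pmax(re_long / re_trans, re_trans / re_long))
}

#' Synthetic tissue phantom with fully developed speckle
#'
#' Draws a uniform random field of point scatterers with standard-normal
#' amplitudes over the imaging plane, dense enough for fully developed
#' speckle (>= 10 scatterers per resolution cell at the default density),
#' and attaches the mechanical ground truth.
#'
#' @param mech A [mech_layer()] tibble (one row per layer).
#' @param seed Integer seed; the scatterer field is reproducible.
#' @param z_range_mm,lat_range_mm Scatterer extent (depth / lateral), mm.
#'   The default depth range extends well below the imaged window so that
#'   tissue compressed toward the transducer stays filled.
#' @param density_per_mm2 Scatterers per square millimetre.
#' @param n_lines,fov_mm Lateral beam lines (evenly spaced) and field of
#'   view: defaults 40 lines over 2 cm.
#' @param focal_depth_mm ARFI focal depth, mm.
#' @return An object of class `tissue_phantom`.
#' @export
tissue_phantom <- function(mech, seed = 1L, z_range_mm = c(12, 34),
                           lat_range_mm = c(-10.5, 10.5),
                           density_per_mm2 = 60, n_lines = 40, fov_mm = 20,
                           focal_depth_mm = 20) {
  stopifnot(is.data.frame(mech), nrow(mech) >= 1)
  area <- diff(z_range_mm) * diff(lat_range_mm)
  n <- round(area * density_per_mm2)
  sc <- with_seed_(seed, tibble::tibble(
    axial_mm = runif(n, z_range_mm[1], z_range_mm[2]),
    lateral_mm = runif(n, lat_range_mm[1], lat_range_mm[2]),
    amplitude = rnorm(n)
  ))
  # layer identity fixed at creation (zero compression depths)
  sc$layer <- findInterval(sc$axial_mm, sort(unique(mech$z_top_mm[-1])),
                           left.open = TRUE) + 1L
  if (nrow(mech) == 1) sc$layer <- 1L
  pitch <- fov_mm / n_lines
  structure(list(
    scatterers = sc, mech = mech, seed = as.integer(seed),
    z_range_mm = z_range_mm, lat_range_mm = lat_range_mm,
    density_per_mm2 = density_per_mm2,
    line_lat_mm = seq(-fov_mm / 2 + pitch / 2, fov_mm / 2 - pitch / 2,
                      length.out = n_lines),
    fov_mm = fov_mm, focal_depth_mm = focal_depth_mm,
    compression_mm = 0
  ), class = "tissue_phantom")
}

#' Apply axial surface compression to a phantom
#'
#' Compression is modelled as uniform axial strain relative to the focal
#' depth (`strain = compression_mm / focal_depth_mm`, so scatterers shift
#' toward the transducer by exactly `strain * depth`) plus geometric
#' per-millimetre stiffening of all moduli,
#' `modulus * (1 + stiffening_per_mm)^compression_mm`.
#'
#' @param phantom A [tissue_phantom()].
#' @param compression_mm One of 0, 2 or 5 mm (the protocol levels).
#' @return A compressed `tissue_phantom`; 0 mm returns the phantom
#'   unchanged.
#' @export
apply_compression <- function(phantom, compression_mm) {
  stopifnot(inherits(phantom, "tissue_phantom"))
  if (!compression_mm %in% c(0, 2, 5)) {
    stop("`compression_mm` must be 0, 2 or 5 (protocol compression levels)",
         call. = FALSE)
  }
  if (compression_mm == 0) return(phantom)
  if (phantom$compression_mm != 0) {
    stop("phantom is already compressed; start from the 0 mm phantom",
         call. = FALSE)
  }
  strain <- compression_mm / phantom$focal_depth_mm
  out <- phantom
  out$scatterers$axial_mm <- phantom$scatterers$axial_mm * (1 - strain)
  gain <- (1 + phantom$mech$stiffening_per_mm)^compression_mm
  for (col in c("re_long", "re_trans", "rv_long", "rv_trans")) {
    out$mech[[col]] <- phantom$mech[[col]] * gain
  }
  out$mech$z_top_mm <- phantom$mech$z_top_mm * (1 - strain)
  out$mech$z_bot_mm <- phantom$mech$z_bot_mm * (1 - strain)
  out$compression_mm <- compression_mm
  out
}

# per-layer (re, rv) at a probe angle for a (possibly compressed) phantom
layer_moduli_at_angle <- function(mech, angle_deg) {
  tibble::tibble(
    re = modulus_at_angle(mech$re_long, mech$re_trans, mech$aos_deg,
                          angle_deg),
    rv = modulus_at_angle(mech$rv_long, mech$rv_trans, mech$aos_deg,
                          angle_deg)
  )
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat(sprintf(
    "Tissue phantom: %d scatterers, %d layer(s), %d lines over %g mm, focal depth %g mm, compression %g mm\n",
    nrow(x$scatterers), nrow(x$mech), length(x$line_lat_mm), x$fov_mm,
    x$focal_depth_mm, x$compression_mm))
  invisible(x)
}
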