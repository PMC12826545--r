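# Independent oracles and shared fixtures for the test suite.

# Fourth-order Runge-Kutta integration of the mass-spring-damper ODE with
# the two-push rectangular forcing; independent of the closed-form solver.
rk4_msd <- function(re, rv, timing, dt = 1e-4, m0 = visr_mass()) {
  ps <- push_starts_ms(timing)
  tau <- push_duration_ms(timing)
  te <- event_times(timing)
  deriv <- function(t, x, v) {
    ff <- if ((t >= ps[1] && t < ps[1] + tau) ||
              (t >= ps[2] && t < ps[2] + tau)) 1 else 0
    c(v, (ff - rv * v - re * x) / m0)
  }
  n <- ceiling(max(te) / dt)
  x <- 0; v <- 0; t <- 0
  out <- numeric(length(te)); oi <- 1
  for (i in seq_len(n)) {
    while (oi <= length(te) && te[oi] <= t + 1e-12) {
      out[oi] <- x; oi <- oi + 1
    }
    k1 <- deriv(t, x, v)
    k2 <- deriv(t + dt / 2, x + dt / 2 * k1[1], v + dt / 2 * k1[2])
    k3 <- deriv(t + dt / 2, x + dt / 2 * k2[1], v + dt / 2 * k2[2])
    k4 <- deriv(t + dt, x + dt * k3[1], v + dt * k3[2])
    x <- x + dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    v <- v + dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
    t <- t + dt
  }
  while (oi <= length(te)) { out[oi] <- x; oi <- oi + 1 }
  out
}

# Small homogeneous phantom (reduced lateral extent) for fast unit tests;
# axial sampling and kernel geometry match the full protocol.
small_phantom <- function(seed = 42, re = 0.04, rv = 0.015) {
  tissue_phantom(mech_layer(re, re, rv, rv), seed = seed,
                 z_range_mm = c(14, 30), lat_range_mm = c(-3.2, 3.2),
                 n_lines = 10, fov_mm = 5)
}

small_rf <- function(phantom = small_phantom(), snr_db = 20, seed = 7,
                     disp_schedule = NULL, timing = visr_timing()) {
  synthesize_rf(phantom, timing, snr_db = snr_db, seed = seed,
                window_mm = c(17, 23), disp_schedule = disp_schedule)
}

# construct a visr_maps object directly (for ROI unit tests)
fake_maps <- function(values, axial_mm, lateral_mm) {
  structure(list(pd = values, re = values, rv = values,
                 fit_error = values * 0,
                 n_valid = matrix(55L, nrow(values), ncol(values)),
                 valid = !is.na(values), axial_mm = axial_mm,
                 lateral_mm = lateral_mm, compression_mm = 0, angle_deg = 0,
                 focal_depth_mm = 20, ground_truth = NULL),
            class = "visr_maps")
}
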