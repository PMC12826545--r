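#' Nominal mass constant of the mass-spring-damper model
#'
#' The VisR mass-spring-damper model is fit per unit force, so only the
#' ratios of mass, damper and spring constants to the (unknown) applied force
#' are identifiable.  The package fixes the relative mass at a small nominal
#' value, placing the model in the inertia-negligible (Voigt-like) regime
#' typical of soft-tissue ARFI response: micrometre-scale displacement with
#' millisecond recovery.  It is a unit convention shared by the generator and
#' the fitter, not an estimated quantity.
#'
#' @return The nominal relative mass (dimensionless module units).
#' @export
visr_mass <- function() 1e-3

# Exact piecewise solution of m x'' + rv x' + re x = F(t) with F piecewise
# constant.  Returns x (and optionally v) at times t (ms).  x in µm.
msd_piecewise <- function(re, rv, m0, breaks, force_levels, t) {
  disc <- rv * rv - 4 * m0 * re
  # advance state (x, v) by dt under constant force F
  advance <- function(x0, v0, FF, dt) {
    xp <- FF / re
    u0 <- x0 - xp
    if (disc > 1e-12 * rv * rv) {
      sq <- sqrt(disc)
      s1 <- (-rv + sq) / (2 * m0)
      s2 <- (-rv - sq) / (2 * m0)
      c1 <- (v0 - s2 * u0) / (s1 - s2)
      c2 <- u0 - c1
      e1 <- exp(s1 * dt)
      e2 <- exp(s2 * dt)
      list(x = xp + c1 * e1 + c2 * e2, v = c1 * s1 * e1 + c2 * s2 * e2)
    } else if (disc < -1e-12 * rv * rv) {
      al <- -rv / (2 * m0)
      om <- sqrt(-disc) / (2 * m0)
      A <- u0
      B <- (v0 - al * u0) / om
      ea <- exp(al * dt)
      co <- cos(om * dt)
      si <- sin(om * dt)
      list(x = xp + ea * (A * co + B * si),
           v = ea * ((al * A + B * om) * co + (al * B - A * om) * si))
    } else {
      al <- -rv / (2 * m0)
      A <- u0
      B <- v0 - al * u0
      ea <- exp(al * dt)
      list(x = xp + ea * (A + B * dt), v = ea * (B + al * (A + B * dt)))
    }
  }
  # segment boundaries: (-Inf, b1], (b1, b2], ...
  seg_t0 <- c(breaks[1], breaks)
  seg_t1 <- c(breaks, Inf)
  x <- numeric(length(t))
  st <- list(x = 0, v = 0)
  for (s in seq_along(seg_t0)) {
    FF <- force_levels[s]
    in_seg <- t > seg_t0[s] & t <= seg_t1[s]
    if (s == 1) in_seg <- t <= seg_t1[1]
    if (any(in_seg)) {
      if (s == 1) {
        x[in_seg] <- 0 # quiescent before the first push
      } else {
        dts <- t[in_seg] - seg_t0[s]
        x[in_seg] <- vapply(dts, function(d) advance(st$x, st$v, FF, d)$x,
                            numeric(1))
      }
    }
    if (is.finite(seg_t1[s]) && s > 1) {
      st <- advance(st$x, st$v, FF, seg_t1[s] - seg_t0[s])
    }
  }
  x
}

# fast numeric MSD displacement curve (µm) at times t (ms)
msd_curve <- function(re, rv, timing, t = event_times(timing),
                      m0 = visr_mass(), force = 1) {
  ps <- push_starts_ms(timing)
  tau <- push_duration_ms(timing)
  if (ps[1] + tau > ps[2]) {
    stop("push windows overlap", call. = FALSE)
  }
  breaks <- c(ps[1], ps[1] + tau, ps[2], ps[2] + tau)
  force_levels <- c(0, force, 0, force, 0)
  msd_piecewise(re, rv, m0, breaks, force_levels, t)
}

#' Mass-spring-damper displacement response to the two-push ARFI sequence
#'
#' Solves `m0 x'' + rv x' + re x = f(t)` exactly (piecewise closed form of
#' the linear ODE, not a numeric integrator), with `f(t) = force` during each
#' push window (duration `push_cycles / push_freq`) and 0 otherwise, from
#' rest initial conditions `x(0) = x'(0) = 0`.  Time starts at the first
#' reference event.
#'
#' `re` is the relative elasticity (spring constant per unit force, 1/µm) and
#' `rv` the relative viscosity (damper constant per unit force, ms/µm): the
#' steady-state displacement under sustained unit force is `1/re` µm, and the
#' post-push recovery time constant is approximately `rv/re` ms.
#'
#' @param re Relative elasticity (> 0), 1/µm per unit force.
#' @param rv Relative viscosity (> 0), ms/µm per unit force.
#' @param timing A [visr_timing()] object defining the push schedule.
#' @param t Slow-time grid (ms); defaults to the ensemble event times.
#' @param m0 Nominal relative mass ([visr_mass()]); a fixed unit convention.
#' @param force Push force amplitude (default 1: responses are per unit
#'   force).
#'
#' @return A tibble with columns `time_ms` and `disp_um`.
#' @examples
#' resp <- msd_response(0.03, 0.01, visr_timing())
#' max(resp$disp_um) # peak displacement, µm
#' @export
msd_response <- function(re, rv, timing = visr_timing(),
                         t = event_times(timing), m0 = visr_mass(),
                         force = 1) {
  stopifnot_positive(re, "re")
  stopifnot_positive(rv, "rv")
  stopifnot_positive(m0, "m0")
  tibble::tibble(time_ms = t,
                 disp_um = msd_curve(re, rv, timing, t, m0, force))
}
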