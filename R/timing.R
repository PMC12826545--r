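#' VisR slow-time sequence timing
#'
#' Describes the two-push ARFI ensemble: reference pulses, a first push,
#' tracking pulses between the pushes, a second push, and a tail of tracking
#' pulses, all on the pulse-repetition-interval grid.  Defaults reproduce the
#' clinical sequence: 2 reference pulses, 2 excitations separated by 8
#' tracking pulses, 43 further tracking pulses, 11.5 kHz PRF, 300-cycle
#' pushes at 4.21 MHz, 6.15 MHz tracking.
#'
#' @param n_reference Number of reference (pre-push) events.
#' @param n_tracks_between Tracking events between the two pushes.
#' @param n_tracks_after Tracking events after the second push.
#' @param prf_khz Pulse repetition frequency, kHz.
#' @param push_cycles Cycles per ARFI excitation.
#' @param push_freq_mhz Push centre frequency, MHz.
#' @param track_freq_mhz Tracking centre frequency, MHz.
#'
#' @return An object of class `visr_timing`.
#' @examples
#' tm <- visr_timing()
#' n_events(tm)          # 55
#' push_duration_ms(tm)  # ~0.0713
#' push_gap_ms(tm)       # ~0.696
#' @export
visr_timing <- function(n_reference = 2, n_tracks_between = 8,
                        n_tracks_after = 43, prf_khz = 11.5,
                        push_cycles = 300, push_freq_mhz = 4.21,
                        track_freq_mhz = 6.15) {
  stopifnot_positive(prf_khz, "prf_khz")
  stopifnot_positive(push_cycles, "push_cycles")
  stopifnot_positive(push_freq_mhz, "push_freq_mhz")
  stopifnot_positive(track_freq_mhz, "track_freq_mhz")
  stopifnot(n_reference >= 1, n_tracks_between >= 0, n_tracks_after >= 1)
  out <- list(n_reference = as.integer(n_reference),
              n_tracks_between = as.integer(n_tracks_between),
              n_tracks_after = as.integer(n_tracks_after),
              prf_khz = prf_khz, push_cycles = push_cycles,
              push_freq_mhz = push_freq_mhz,
              track_freq_mhz = track_freq_mhz)
  if (push_duration_ms_(out) >= 1 / prf_khz) {
    stop("push duration exceeds the pulse repetition interval: push windows would overlap tracking events", call. = FALSE)
  }
  structure(out, class = "visr_timing")
}

push_duration_ms_ <- function(tm) tm$push_cycles / tm$push_freq_mhz / 1000

#' @rdname visr_timing
#' @param timing A `visr_timing` object.
#' @export
n_events <- function(timing) {
  timing$n_reference + 2L + timing$n_tracks_between + timing$n_tracks_after
}

#' Slow-time event times in milliseconds
#'
#' Event 1 (the first reference pulse) is at time 0; events are spaced by the
#' pulse repetition interval.
#'
#' @param timing A [visr_timing()] object.
#' @return Numeric vector of length [n_events()].
#' @export
event_times <- function(timing) {
  (seq_len(n_events(timing)) - 1) / timing$prf_khz
}

#' @rdname event_times
#' @details `push_event_index()` gives the (1-based) slow-time indices of the
#'   two excitation events; `push_starts_ms()` the corresponding start times.
#' @export
push_event_index <- function(timing) {
  p1 <- timing$n_reference + 1L
  c(p1, p1 + timing$n_tracks_between + 1L)
}

#' @rdname event_times
#' @export
push_starts_ms <- function(timing) {
  (push_event_index(timing) - 1) / timing$prf_khz
}

#' @rdname event_times
#' @details `push_duration_ms()` is `push_cycles / push_freq`;
#'   `push_gap_ms()` is the span of the tracking intervals between the two
#'   excitations (`n_tracks_between / prf`).
#' @export
push_duration_ms <- function(timing) push_duration_ms_(timing)

#' @rdname event_times
#' @export
push_gap_ms <- function(timing) timing$n_tracks_between / timing$prf_khz

#' @export
print.visr_timing <- function(x, ...) {
  cat("VisR sequence timing\n")
  cat(sprintf("  events: %d (%d ref + 2 push + %d between + %d after)\n",
              n_events(x), x$n_reference, x$n_tracks_between,
              x$n_tracks_after))
  cat(sprintf("  PRF %.2f kHz; push %d cycles @ %.2f MHz (%.1f us); track @ %.2f MHz\n",
              x$prf_khz, x$push_cycles, x$push_freq_mhz,
              1000 * push_duration_ms(x), x$track_freq_mhz))
  invisible(x)
}
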