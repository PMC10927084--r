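# Stimulation schedules and clamp directives.

.new_protocol <- function(kind, amplitude, duration, starts, ...) {
  if (amplitude <= 0) stop("stimulus amplitude must be positive")
  if (duration <= 0) stop("stimulus duration must be positive")
  structure(list(kind = kind, amplitude = amplitude, duration = duration,
                 starts = as.numeric(starts), ...),
            class = "stim_protocol")
}

#' Stimulation protocols
#'
#' `stim_single()` delivers one pulse at t = 0; `stim_s1s1()` paces at a
#' fixed interval; `stim_s1s2()` delivers `n_s1` beats at the S1 interval
#' followed by a final beat after the S2 interval.  The default pulse is
#' 1 ms, 40 pA/pF.
#'
#' @param amplitude pulse amplitude (pA/pF).
#' @param duration pulse duration (ms).
#' @param interval,s1_interval,s2_interval pacing intervals (ms); must exceed
#'   the pulse duration.
#' @param n_s1 number of S1 beats.
#' @return A `stim_protocol` object with the pulse start times.
#' @export
stim_single <- function(amplitude = 40, duration = 1) {
  .new_protocol("single", amplitude, duration, 0)
}

#' @rdname stim_single
#' @export
stim_none <- function() {
  .new_protocol("none", 40, 1, numeric(0))
}

#' @rdname stim_single
#' @export
stim_s1s1 <- function(interval = 3000, n_s1 = 3, amplitude = 40,
                      duration = 1) {
  if (interval <= duration) stop("pacing interval must exceed pulse duration")
  if (n_s1 < 1) stop("n_s1 must be at least 1")
  .new_protocol("S1S1", amplitude, duration,
                seq(0, by = interval, length.out = n_s1),
                s1_interval = interval, n_s1 = n_s1)
}

#' @rdname stim_single
#' @export
stim_s1s2 <- function(s1_interval = 1000, s2_interval = 2000, n_s1 = 3,
                      amplitude = 40, duration = 1) {
  if (s1_interval <= duration || s2_interval <= duration)
    stop("pacing intervals must exceed pulse duration")
  if (n_s1 < 1) stop("n_s1 must be at least 1")
  starts <- c(seq(0, by = s1_interval, length.out = n_s1),
              (n_s1 - 1) * s1_interval + s2_interval)
  .new_protocol("S1S2", amplitude, duration, starts,
                s1_interval = s1_interval, s2_interval = s2_interval,
                n_s1 = n_s1)
}

#' Evaluate the stimulus current of a protocol
#'
#' @param protocol a `stim_protocol`.
#' @param t numeric vector of times (ms).
#' @return Stimulus current density (pA/pF) at each time.
#' @export
stim_current <- function(protocol, t) {
  stopifnot(inherits(protocol, "stim_protocol"))
  out <- numeric(length(t))
  for (s in protocol$starts)
    out[t >= s & t < s + protocol$duration] <- protocol$amplitude
  out
}

.new_clamp <- function(target, mode, value = NA_real_, end_value = NA_real_,
                       scale = 1, window, ref = numeric(0), ref_t0 = 0,
                       ref_dt = 1) {
  target <- match.arg(target, c("Ca_sub", "V_m", "I_CaL", "I_NCX"))
  window <- as.numeric(window)
  if (length(window) != 2 || !(window[1] < window[2]))
    stop("clamp window must satisfy t_on < t_off")
  structure(list(target = target, mode = as.integer(mode), value = value,
                 end_value = end_value, scale = scale,
                 t_on = window[1], t_off = window[2],
                 ref = ref, ref_t0 = ref_t0, ref_dt = ref_dt),
            class = "clamp_directive")
}

#' Clamp directives
#'
#' `clamp_constant()` holds the target at a fixed level inside the window
#' (for a current target, `value = NA` means "the current's free-running
#' value when the window opens", matching clamping at the plateau level).
#' `make_scaled_trace_clamp()` makes the target follow `scale` times a
#' signal of a reference trace.  `make_ramp_clamp()` leaves a current free
#' before the takeoff time and then replaces it by a linear interpolation
#' from its value at takeoff to `end_value` at the window end.
#'
#' Clamping `Ca_sub` sets the junctional and subsarcolemmal Ca
#' concentrations simultaneously to the same value; a clamped current is
#' substituted both in the voltage equation and in the Ca-flux equations.
#' A directive never modifies the state outside its window.
#'
#' @param target one of `"Ca_sub"`, `"V_m"`, `"I_CaL"`, `"I_NCX"`.
#' @param value clamp level in target units (mM, mV, or A/F).
#' @param window numeric `c(t_on, t_off)` in ms with `t_on < t_off`.
#' @param trace reference `wg_trace` covering the window.
#' @param signal column of the reference trace to follow.
#' @param scale non-negative scaling of the reference signal.
#' @param takeoff_time ramp start (ms); must lie inside the window.
#' @param end_value current level (A/F) reached at the window end.
#' @return A `clamp_directive`.
#' @export
clamp_constant <- function(target, value = NA_real_, window) {
  .new_clamp(target, 0L, value = value, window = window)
}

#' @rdname clamp_constant
#' @export
make_scaled_trace_clamp <- function(target, trace, signal = "Ca_sub_mM",
                                    scale = 1, window) {
  if (scale < 0) stop("scale must be non-negative")
  if (!signal %in% names(trace)) stop("unknown signal: ", signal)
  t <- trace$t_ms
  if (window[1] < t[1] || window[1] > t[length(t)])
    stop("reference trace does not cover the clamp-window start")
  # beyond the reference end the clamp holds the trace's final value
  .new_clamp(target, 1L, scale = scale, window = window,
             ref = as.numeric(trace[[signal]]),
             ref_t0 = t[1], ref_dt = diff(t[1:2]))
}

#' @rdname clamp_constant
#' @export
make_ramp_clamp <- function(target, takeoff_time, end_value, window) {
  if (takeoff_time < window[1] || takeoff_time >= window[2])
    stop("takeoff_time must lie inside the clamp window")
  .new_clamp(target, 2L, end_value = end_value,
             window = c(takeoff_time, window[2]))
}

#' Oscillation range of a signal, for constant clamp levels
#'
#' Returns the lowest and highest level of a signal over a window, the
#' levels at which the signal is clamped in the dissection protocols.
#'
#' @param trace a trace.
#' @param signal trace column name.
#' @param window numeric `c(t_on, t_off)` in ms.
#' @return Named numeric `c(lowest, highest)`.
#' @export
clamp_levels_from_trace <- function(trace, signal = "Ca_sub_mM", window) {
  if (!signal %in% names(trace)) stop("unknown signal: ", signal)
  sel <- trace$t_ms >= window[1] & trace$t_ms <= window[2]
  if (!any(sel)) stop("empty clamp window")
  x <- trace[[signal]][sel]
  c(lowest = min(x), highest = max(x))
}

#' Default clamp-onset time for the EAD phase
#'
#' The takeoff time of the first detected EAD or, if none is detected, the
#' first time after the upstroke at which V_m falls below `fallback_mV`.
#'
#' @param trace a trace.
#' @param fallback_mV fallback voltage threshold (mV).
#' @return Onset time (ms), or `NA` if the trace has no upstroke.
#' @export
ead_phase_onset <- function(trace, fallback_mV = 20) {
  ev <- detect_eads(trace)
  if (nrow(ev) > 0) return(ev$takeoff_time[1])
  v <- trace$V_m_mV
  up <- which(v > 0)[1]
  if (is.na(up)) return(NA_real_)
  below <- which(trace$t_ms > trace$t_ms[up] & v < fallback_mV)[1]
  if (is.na(below)) NA_real_ else trace$t_ms[below]
}
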