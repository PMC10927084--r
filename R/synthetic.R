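# Synthetic V_m/[Ca]_sub trace pairs with controlled EAD morphology, used to
# test the detectors and the classifier's baseline stage without the full
# model.

#' Specification of a synthetic AP trace
#'
#' @param resting_vm,plateau_vm resting and plateau voltages (mV).
#' @param apd_base base AP duration before the oscillation phase (ms).
#' @param n_humps number of EAD-like oscillation humps (>= 0).
#' @param hump_amp_vm hump amplitude for V_m (mV).
#' @param hump_amp_ca hump amplitude for Ca (mM).
#' @param period oscillation period (ms).
#' @param phase_lag lag of the Ca oscillation relative to V_m (ms,
#'   positive = Ca later).
#' @param ca_oscillates if `FALSE`, Ca is a single prolonged transient (the
#'   large-Ca-transient morphology).
#' @param noise_sd additive i.i.d. Gaussian noise (same units per signal,
#'   scaled for Ca by the transient amplitude).
#' @param seed integer; identical seeds give identical traces.
#' @param dt sample spacing (ms).
#' @return A `synthetic_trace_spec`.
#' @export
synthetic_trace_spec <- function(resting_vm = -85, plateau_vm = -10,
                                 apd_base = 150, n_humps = 3,
                                 hump_amp_vm = 10, hump_amp_ca = 5e-4,
                                 period = 150, phase_lag = 0,
                                 ca_oscillates = TRUE, noise_sd = 0,
                                 seed = 1, dt = 1) {
  if (period <= 0) stop("period must be positive")
  if (n_humps < 0) stop("n_humps must be non-negative")
  structure(as.list(environment()), class = "synthetic_trace_spec")
}

#' Generate a synthetic V_m/[Ca]_sub trace pair
#'
#' Builds a piecewise AP template: rest, a fast upstroke, decay to the
#' plateau, `n_humps` damped-sinusoid oscillations in the repolarization
#' phase (takeoffs at the constructed minima), then final repolarization.
#' The Ca series is a phase-shifted copy of the oscillation (or a single
#' prolonged transient when `ca_oscillates` is `FALSE`), plus optional
#' Gaussian noise.
#'
#' @param spec a [synthetic_trace_spec()].
#' @return A `wg_trace` data.frame with columns `t_ms`, `V_m_mV`,
#'   `Ca_sub_mM`, flagged `synthetic` in its attributes; the constructed
#'   hump takeoff times are in `attr(, "hump_takeoffs")`.
#' @export
generate_synthetic_trace <- function(spec) {
  stopifnot(inherits(spec, "synthetic_trace_spec"))
  s <- spec
  t_up <- 20                      # upstroke onset
  t_pl <- t_up + 5                # reach peak, start of plateau decay
  t_osc <- t_pl + s$apd_base      # oscillation phase start
  osc_len <- s$n_humps * s$period
  t_rep <- t_osc + osc_len        # final repolarization start
  t_end <- t_rep + 200
  t <- seq(0, t_end, by = s$dt)
  peak <- 30
  decay_target <- s$plateau_vm

  v <- rep(s$resting_vm, length(t))
  ca <- rep(1e-4, length(t))

  up <- t >= t_up & t < t_pl
  v[up] <- s$resting_vm + (peak - s$resting_vm) * (t[up] - t_up) / (t_pl - t_up)
  pl <- t >= t_pl & t < t_osc
  v[pl] <- decay_target + (peak - decay_target) * exp(-(t[pl] - t_pl) / 25)

  takeoffs <- numeric(0)
  if (s$n_humps > 0) {
    osc <- t >= t_osc & t < t_rep
    tau <- t[osc] - t_osc
    damp <- exp(-tau / (2 * s$period))
    v[osc] <- decay_target +
      s$hump_amp_vm * damp * (1 - cos(2 * pi * tau / s$period)) / 2 -
      5 * tau / max(osc_len, 1)
    takeoffs <- t_osc + s$period * seq(0, s$n_humps - 1)
  }
  rp <- t >= t_rep
  v_at_rep <- if (s$n_humps > 0) decay_target - 5 else decay_target
  v[rp] <- pmax(s$resting_vm,
                v_at_rep + (s$resting_vm - v_at_rep) * (t[rp] - t_rep) / 120)

  ca_peak <- 10 * s$hump_amp_ca + 5e-4
  trans <- t >= t_up
  if (isTRUE(s$ca_oscillates)) {
    # fast decay to a plateau so the oscillation phase rides on a near-flat
    # baseline and every hump clears the prominence threshold
    ca_plateau <- 8e-4
    ca[trans] <- ca_plateau + (ca_peak - ca_plateau) *
      exp(-(t[trans] - t_up) / 60)
    if (s$n_humps > 0) {
      osc <- t >= t_osc & t < t_rep
      tau <- t[osc] - t_osc
      damp <- exp(-tau / (2 * s$period))
      ca[osc] <- ca[osc] +
        s$hump_amp_ca * damp *
        (1 - cos(2 * pi * (tau - s$phase_lag) / s$period)) / 2
    }
    rp2 <- t >= t_rep
    ca[rp2] <- pmax(1e-4, ca_plateau * exp(-(t[rp2] - t_rep) / 150))
  } else {
    # single prolonged transient spanning the oscillation phase
    rise <- 1 - exp(-(t[trans] - t_up) / 50)
    fall <- exp(-pmax(0, t[trans] - t_rep) / 150)
    ca[trans] <- 1e-4 + ca_peak * rise * fall
  }

  if (s$noise_sd > 0) {
    # recording-like noise: Gaussian, mildly low-pass filtered (5-sample
    # moving average) so its spectrum resembles digitized optical/patch
    # recordings rather than white sample-to-sample jitter
    set.seed(as.integer(s$seed))
    smooth5 <- function(x) stats::filter(x, rep(1 / 5, 5), circular = TRUE)
    v <- v + as.numeric(smooth5(rnorm(length(v), sd = s$noise_sd * sqrt(5))))
    ca <- ca + as.numeric(smooth5(rnorm(length(ca),
                                        sd = s$noise_sd * sqrt(5) *
                                          ca_peak / 40)))
  }

  out <- data.frame(t_ms = t, V_m_mV = v, Ca_sub_mM = ca)
  attr(out, "spec") <- spec
  attr(out, "synthetic") <- TRUE
  attr(out, "hump_takeoffs") <- takeoffs
  attr(out, "osc_window") <- c(t_osc, t_rep)
  class(out) <- c("wg_trace", "data.frame")
  out
}
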