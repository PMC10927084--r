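# The flattened-f_ss variant and steady-state characterization protocols.

#' Flatten the late rise of a steady-state inactivation curve
#'
#' Returns a curve equal to the input up to the voltage of the curve's
#' minimum and held constant at that minimum for all higher voltages.  The
#' result is non-increasing; applying the rule twice changes nothing.
#'
#' @param curve a `gating_curve` (see [fss_curve()]), tabulated on an
#'   increasing voltage grid.
#' @return A flattened `gating_curve`.
#' @export
flatten_fss <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("V_m_mV", "f_ss") %in% names(curve)))
  if (is.unsorted(curve$V_m_mV, strictly = TRUE))
    stop("curve must be tabulated on an increasing voltage grid")
  k <- which.min(curve$f_ss)
  out <- curve
  out$f_ss[seq_along(out$f_ss) > k] <- curve$f_ss[k]
  attr(out, "variant") <- "flattened"
  class(out) <- c("gating_curve", "data.frame")
  out
}

# a step V_m-clamp waveform as a reference trace for scaled-trace clamps
.step_vm_trace <- function(t_end, t_step, v_hold, v_step, dt = 1) {
  t <- seq(0, t_end, by = dt)
  data.frame(t_ms = t, V_m_mV = ifelse(t < t_step, v_hold, v_step))
}

#' Peak L-type Ca current versus clamped submembrane Ca
#'
#' For each pair of holding voltage and clamped [Ca]_sub level, steps V_m
#' from -80 mV to the holding level (after a settling period) with [Ca]_sub
#' clamped throughout, and records the peak inward I_CaL magnitude after
#' the step.
#'
#' @param holding_vms holding voltages (mV).
#' @param casub_levels clamped [Ca]_sub levels (mM), positive.
#' @param params parameter set.
#' @param settle_ms settling time at -80 mV before the step.
#' @param probe_ms time after the step within which the peak is measured.
#' @return data.frame with `holding_Vm_mV`, `Ca_sub_mM`,
#'   `peak_ICaL_AF` (peak inward magnitude, A/F, non-negative).
#' @export
peak_ical_vs_casub <- function(holding_vms, casub_levels,
                               params = wg_params(), settle_ms = 500,
                               probe_ms = 300) {
  if (any(casub_levels <= 0)) stop("Ca_sub levels must be positive")
  t_end <- settle_ms + probe_ms
  out <- expand.grid(holding_Vm_mV = holding_vms, Ca_sub_mM = casub_levels,
                     KEEP.OUT.ATTRS = FALSE)
  out$peak_ICaL_AF <- NA_real_
  for (i in seq_len(nrow(out))) {
    ref <- .step_vm_trace(t_end, settle_ms, -80, out$holding_Vm_mV[i])
    cl <- list(
      make_scaled_trace_clamp("V_m", ref, "V_m_mV", 1, c(0, t_end)),
      clamp_constant("Ca_sub", out$Ca_sub_mM[i], c(0, t_end)))
    tr <- simulate_ap(params, stim_none(), clamps = cl,
                      t_end = t_end, stride = 10)
    sel <- tr$t_ms >= settle_ms
    out$peak_ICaL_AF[i] <- max(0, -min(tr$I_CaL_AF[sel]))
  }
  out
}

#' Late submembrane Ca versus holding voltage
#'
#' Switches V_m from -80 mV to each holding level and reports the
#' late-time (steady or cycle-mean) [Ca]_sub, optionally with the NCX
#' current or the L-type Ca current removed.
#'
#' @param levels holding voltages (mV), within [-80, 60].
#' @param variant `"full"`, `"zero_NCX"` (NCX density set to 0) or
#'   `"zero_ICaL"` (Ca permeability set to 0).
#' @param params parameter set (the variant's current removal is applied on
#'   top).
#' @param hold_ms holding duration (ms); the value is read over the last
#'   quarter of it.
#' @return data.frame with `holding_Vm_mV`, `Ca_sub_mM` (cycle mean when
#'   oscillating), `oscillating` flag.
#' @export
casub_vs_holding_vm <- function(levels,
                                variant = c("full", "zero_NCX", "zero_ICaL"),
                                params = wg_params(), hold_ms = 20000) {
  variant <- match.arg(variant)
  if (any(levels < -80 | levels > 60))
    stop("holding levels must lie within [-80, 60] mV")
  if (variant == "zero_NCX") params$values[["I_NCX_bar"]] <- 0
  if (variant == "zero_ICaL") params$values[["P_Ca"]] <- 0
  out <- data.frame(holding_Vm_mV = levels, Ca_sub_mM = NA_real_,
                    oscillating = FALSE)
  t_step <- 100
  t_end <- t_step + hold_ms
  for (i in seq_along(levels)) {
    ref <- .step_vm_trace(t_end, t_step, -80, levels[i])
    cl <- list(make_scaled_trace_clamp("V_m", ref, "V_m_mV", 1, c(0, t_end)))
    tr <- simulate_ap(params, stim_none(), clamps = cl,
                      t_end = t_end, stride = 200, on_divergence = "keep")
    late <- tr$t_ms >= t_step + 0.75 * hold_ms
    osc <- detect_oscillations(tr, "Ca_sub_mM",
                               c(t_step + 0.75 * hold_ms, t_end))
    out$Ca_sub_mM[i] <- mean(tr$Ca_sub_mM[late])
    out$oscillating[i] <- osc$n_cycles >= 2
  }
  out
}
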