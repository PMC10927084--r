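# Clamp-experiment orchestration and the four-type EAD mechanism classifier.
#
# Decision tree (fixed order):
#   1. baseline run: no EAD and repolarized -> none; not repolarized (or,
#      under pacing, APD > pacing interval) -> repol_failure.
#   2. exactly one EAD and no Ca_sub oscillation (< 2 cycles), with the
#      0.5x scaled-trace Ca clamp abolishing the EAD -> typeIV; if the EAD
#      survives the halved Ca trace it falls through to the clamp stages.
#   3. clamp Ca_sub at the lowest/highest level of its EAD-phase range:
#      V_m oscillations persist under either -> typeI.
#   4. clamp V_m at the lowest/highest plateau level: Ca_sub oscillations
#      persist under either -> typeII (confirmed by constant I_NCX clamp
#      silencing V_m while Ca persists, and constant I_CaL clamp
#      preserving both).
#   5. otherwise -> typeIII.

.osc_persists <- function(report, n_min = 2L) report$n_cycles >= n_min

.clamp_experiment <- function(params, protocol, directive, t_end, dt, stride,
                              init, window, settle = 100) {
  tr <- simulate_ap(params, protocol, clamps = list(directive),
                    t_end = t_end, dt = dt, stride = stride, init = init,
                    on_divergence = "keep")
  win <- c(window[1] + settle, min(window[2], tr$t_ms[nrow(tr)]))
  vm <- ca <- NULL
  ok <- !isTRUE(attr(tr, "diverged")) && win[1] < win[2]
  if (ok) {
    vm <- detect_oscillations(tr, "V_m_mV", win)
    ca <- detect_oscillations(tr, "Ca_sub_mM", win)
  }
  structure(list(directive = directive,
                 vm_oscillates = if (ok) .osc_persists(vm) else NA,
                 ca_oscillates = if (ok) .osc_persists(ca) else NA,
                 vm_report = vm, ca_report = ca,
                 diverged = !ok, trace = tr),
            class = "clamp_experiment")
}

#' @export
print.clamp_experiment <- function(x, ...) {
  cat(sprintf("<clamp_experiment> %s clamp: V_m %s, Ca %s%s\n",
              x$directive$target,
              if (isTRUE(x$vm_oscillates)) "oscillates" else "silent",
              if (isTRUE(x$ca_oscillates)) "oscillates" else "silent",
              if (x$diverged) " [diverged]" else ""))
  invisible(x)
}

#' Classify the EAD mechanism at a parameter point
#'
#' Runs the baseline simulation and the in-silico clamp experiments
#' (Ca_sub clamp at the extremes of its EAD-phase range, V_m clamp at the
#' plateau extremes, and the confirmatory current clamps), and classifies
#' the EAD mechanism as one of `none`, `repol_failure`, `typeI` (driven by
#' V_m oscillations), `typeII` (driven by Ca oscillations alone), `typeIII`
#' (Ca-I_CaL-V_m-Ca feedback loop) or `typeIV` (single EAD driven by a
#' large Ca transient).
#'
#' @param params a `wg_params` object.
#' @param protocol stimulation protocol; for S1S1/S1S2 pacing the clamp
#'   experiments are applied in the last (S2) beat and repolarization
#'   failure means APD exceeding the pacing interval.
#' @param t_end baseline horizon (ms).
#' @param dt,stride integration step and storage stride.
#' @param clamp_horizon how long each clamped run continues past the clamp
#'   onset (ms).
#' @param with_confirmatory run the confirmatory clamps (type IV scaled
#'   trace, type II current clamps); disabled in large scans for speed.
#' @param osc_min_cycles "oscillations persist" means at least this many
#'   cycles in the clamped window.
#' @param stop_at_repol stop the baseline run early once repolarized.
#' @param init initial state for every run (the single control resting
#'   state by default).
#' @return An `ead_classification` with `label`, `baseline_eads`, `phase`
#'   (when computable), `apd`, and the clamp-experiment `evidence`.
#' @export
classify_ead_mechanism <- function(params, protocol = stim_single(),
                                   t_end = 10000, dt = 0.01, stride = 100,
                                   clamp_horizon = 6000,
                                   with_confirmatory = TRUE,
                                   osc_min_cycles = 2L,
                                   stop_at_repol = TRUE,
                                   init = wg_initial_state()) {
  stopifnot(inherits(params, "wg_params"))
  base <- simulate_ap(params, protocol, t_end = t_end, dt = dt,
                      stride = stride, init = init,
                      stop_at_repol = stop_at_repol,
                      on_divergence = "keep")
  out <- structure(list(label = NA_character_, baseline_eads = NULL,
                        phase = NULL, apd = NULL, evidence = list(),
                        notes = character(0), params = params,
                        protocol = protocol, baseline = base),
                   class = "ead_classification")
  if (isTRUE(attr(base, "diverged"))) {
    out$label <- "diverged"
    out$notes <- sprintf("baseline divergence at t = %.1f ms",
                         attr(base, "t_diverged"))
    return(out)
  }

  paced <- protocol$kind != "single"
  # for paced protocols classify the final (S2) beat
  beat_start <- if (paced) protocol$starts[length(protocol$starts)] else 0
  pacing_int <- if (paced) min(diff(c(protocol$starts, t_end))) else NA_real_

  apd <- tryCatch(measure_apd(base, from = beat_start),
                  error = function(e) NULL)
  out$apd <- apd
  if (is.null(apd)) {   # no upstroke at all
    out$label <- "none"
    out$notes <- "no stimulus-evoked upstroke"
    return(out)
  }
  failed <- if (paced) {
    !apd$repolarized || (is.finite(apd$APD) && apd$APD > pacing_int)
  } else !apd$repolarized

  eads <- detect_eads(base, window = c(beat_start, base$t_ms[nrow(base)]))
  out$baseline_eads <- eads

  if (failed) { out$label <- "repol_failure"; return(out) }
  if (nrow(eads) == 0) { out$label <- "none"; return(out) }

  # EAD-phase window of the baseline: first takeoff to final repolarization
  t_on <- eads$takeoff_time[1]
  t_off_base <- if (isTRUE(apd$repolarized)) {
    apd$upstroke_time + apd$APD
  } else base$t_ms[nrow(base)]
  win_base <- c(t_on, t_off_base)
  ca_osc <- detect_oscillations(base, "Ca_sub_mM", win_base)
  vm_osc <- detect_oscillations(base, "V_m_mV", win_base)
  out$phase <- tryCatch(phase_relation(base, win_base),
                        error = function(e) NULL)

  t_end_cl <- min(t_end, t_on + clamp_horizon)
  win_cl <- c(t_on, t_end_cl)
  # clamp levels are read over the EAD oscillation span itself (first
  # takeoff to last EAD peak), not the final repolarization descent
  win_lev <- c(t_on, max(t_on + 1, max(eads$peak_time)))

  # ---- stage 2: large-Ca-transient EADs ----
  # candidate: exactly one EAD without a Ca oscillation (a single passive Ca
  # bump riding on the lone EAD does not count; "oscillates" means at least
  # 2 cycles throughout the tree).  The call is confirmed by clamping Ca_sub
  # to 0.5 times its own trace: a transient-driven EAD disappears, a
  # voltage-driven one persists and falls through to the clamp stages.
  if (nrow(eads) == 1 && ca_osc$n_cycles < 2) {
    dir4 <- make_scaled_trace_clamp("Ca_sub", base, "Ca_sub_mM",
                                    scale = 0.5, window = win_cl)
    ex <- .clamp_experiment(params, protocol, dir4, t_end_cl, dt, stride,
                            init, win_cl)
    ev_eads <- if (!ex$diverged)
      detect_eads(ex$trace, window = c(t_on, t_end_cl)) else NULL
    ex$ead_abolished <- !is.null(ev_eads) && nrow(ev_eads) == 0
    out$evidence <- c(out$evidence, list(ca_half_trace = ex))
    if (isTRUE(ex$ead_abolished)) {
      out$label <- "typeIV"
      return(out)
    }
  }

  # ---- stage 3: Ca_sub clamps at the extremes of its EAD-phase range ----
  lv <- clamp_levels_from_trace(base, "Ca_sub_mM", win_lev)
  ex_lo <- .clamp_experiment(params, protocol,
                             clamp_constant("Ca_sub", lv[["lowest"]], win_cl),
                             t_end_cl, dt, stride, init, win_cl)
  ex_hi <- .clamp_experiment(params, protocol,
                             clamp_constant("Ca_sub", lv[["highest"]], win_cl),
                             t_end_cl, dt, stride, init, win_cl)
  out$evidence <- c(out$evidence,
                    list(ca_clamp_low = ex_lo, ca_clamp_high = ex_hi))
  uncertain <- ex_lo$diverged && ex_hi$diverged
  if (isTRUE(ex_lo$vm_oscillates) || isTRUE(ex_hi$vm_oscillates)) {
    out$label <- "typeI"
    return(out)
  }

  # ---- stage 4: V_m clamps at the plateau extremes ----
  vlv <- clamp_levels_from_trace(base, "V_m_mV", win_lev)
  vx_lo <- .clamp_experiment(params, protocol,
                             clamp_constant("V_m", vlv[["lowest"]], win_cl),
                             t_end_cl, dt, stride, init, win_cl)
  vx_hi <- .clamp_experiment(params, protocol,
                             clamp_constant("V_m", vlv[["highest"]], win_cl),
                             t_end_cl, dt, stride, init, win_cl)
  out$evidence <- c(out$evidence,
                    list(vm_clamp_low = vx_lo, vm_clamp_high = vx_hi))
  uncertain <- uncertain || (vx_lo$diverged && vx_hi$diverged)
  if (isTRUE(vx_lo$ca_oscillates) || isTRUE(vx_hi$ca_oscillates)) {
    out$label <- "typeII"
    if (with_confirmatory) {
      nx <- .clamp_experiment(params, protocol,
                              clamp_constant("I_NCX", NA_real_, win_cl),
                              t_end_cl, dt, stride, init, win_cl)
      cx <- .clamp_experiment(params, protocol,
                              clamp_constant("I_CaL", NA_real_, win_cl),
                              t_end_cl, dt, stride, init, win_cl)
      out$evidence <- c(out$evidence,
                        list(incx_clamp = nx, ical_clamp = cx))
      if (isTRUE(nx$vm_oscillates))
        out$notes <- c(out$notes,
                       "V_m oscillations not abolished by I_NCX clamp")
    }
    return(out)
  }

  out$label <- "typeIII"
  if (uncertain)
    out$notes <- c(out$notes,
                   "uncertain: clamp runs diverged, oscillation persistence untestable")
  out
}

#' @export
print.ead_classification <- function(x, ...) {
  cat("<ead_classification>", x$label, "\n")
  if (!is.null(x$baseline_eads))
    cat("  baseline EADs:", nrow(x$baseline_eads), "\n")
  if (!is.null(x$phase))
    cat("  phase:", x$phase$label,
        sprintf("(lag %.1f ms)", x$phase$lag_ms), "\n")
  for (nm in names(x$evidence)) {
    e <- x$evidence[[nm]]
    cat(sprintf("  %s: V_m %s, Ca %s\n", nm,
                if (isTRUE(e$vm_oscillates)) "osc" else "silent",
                if (isTRUE(e$ca_oscillates)) "osc" else "silent"))
  }
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
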