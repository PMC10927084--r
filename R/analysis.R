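# Trace analysis: APD, EAD detection, oscillation counting, V_m-Ca phase.

# alternating extrema of a series by sign changes of the first difference,
# then persistence-style pruning of oscillations smaller than `thr`
.extrema <- function(x, thr) {
  n <- length(x)
  if (n < 3) return(list(idx = integer(0), kind = integer(0)))
  d <- diff(x)
  s <- sign(d)
  # carry the last nonzero slope through flat stretches
  nz <- s != 0
  if (!any(nz)) return(list(idx = integer(0), kind = integer(0)))
  fill <- cummax(ifelse(nz, seq_along(s), 0L))
  fill[fill == 0L] <- which(nz)[1]   # leading flat: use first nonzero slope
  s <- s[fill]
  turn <- which(diff(s) != 0) + 1L
  if (!length(turn)) return(list(idx = integer(0), kind = integer(0)))
  kind <- ifelse(s[turn] < s[pmax(turn - 1L, 1L)], 1L, -1L)  # 1 max, -1 min
  idx <- turn
  # prune adjacent extrema pairs with range below threshold
  repeat {
    if (length(idx) < 2) break
    amp <- abs(diff(x[idx]))
    k <- which.min(amp)
    if (amp[k] >= thr) break
    idx <- idx[-c(k, k + 1L)]
    kind <- kind[-c(k, k + 1L)]
  }
  list(idx = idx, kind = kind)
}

.window_sel <- function(trace, window) {
  t <- trace$t_ms
  if (is.null(window)) return(rep(TRUE, length(t)))
  if (window[1] > t[length(t)] || window[2] < t[1])
    stop("window lies outside the trace")
  t >= window[1] & t <= window[2]
}

#' Action potential duration and repolarization
#'
#' APD is the time from the upstroke (first upward crossing of the
#' repolarization threshold at or after `from`) to the first downward
#' crossing of the same threshold.  `repolarized` is `FALSE` when no
#' downward crossing occurs before the end of the trace.
#'
#' @param trace a trace containing a stimulus-evoked upstroke.
#' @param repol_threshold repolarization threshold (mV).
#' @param from search for the upstroke from this time (ms).
#' @return List with `APD` (ms, `NA` if not repolarized), `repolarized`,
#'   `upstroke_time`.
#' @export
measure_apd <- function(trace, repol_threshold = -75, from = 0) {
  t <- trace$t_ms
  v <- trace$V_m_mV
  i0 <- which(t >= from)[1]
  if (is.na(i0)) stop("no samples at or after `from`")
  up <- which(t >= from & v > repol_threshold &
              c(-Inf, v[-length(v)]) <= repol_threshold)[1]
  if (is.na(up) || max(v[t >= from]) < 0)
    stop("no stimulus-evoked upstroke found")
  dn <- which(t > t[up] & v < repol_threshold &
              c(Inf, v[-length(v)]) >= repol_threshold)[1]
  if (is.na(dn))
    return(list(APD = NA_real_, repolarized = FALSE, upstroke_time = t[up]))
  list(APD = t[dn] - t[up], repolarized = TRUE, upstroke_time = t[up])
}

#' Detect early afterdepolarizations
#'
#' An EAD is registered where dV_m/dt (central differences on the stored
#' grid) crosses from negative to positive while V_m lies within the
#' plateau/repolarization voltage band, and the subsequent local maximum
#' exceeds the takeoff voltage by at least `min_amplitude`.
#'
#' @param trace a trace sampled at 1 ms or finer.
#' @param window numeric `c(t_on, t_off)` or `NULL` for the whole trace
#'   after the first upstroke.
#' @param band takeoff voltage band (mV); excludes the upstroke and resting
#'   fluctuations.
#' @param min_amplitude minimal peak-minus-takeoff amplitude (mV).
#' @param min_duration minimal takeoff-to-peak duration (ms); EADs evolve
#'   over tens of milliseconds, so faster excursions are discarded as noise.
#' @param smooth_ms centered moving-average window applied to V_m before
#'   extremum detection (ms; 0 disables).  The default is far below the
#'   EAD timescale and suppresses sample noise on recorded traces.
#' @return data.frame with one row per event: `takeoff_time`,
#'   `takeoff_voltage`, `peak_time`, `peak_voltage`, `amplitude`.
#' @export
detect_eads <- function(trace, window = NULL, band = c(-70, 20),
                        min_amplitude = 1, min_duration = 10,
                        smooth_ms = 15) {
  t <- trace$t_ms
  v <- trace$V_m_mV
  if (smooth_ms > 0 && length(t) > 5) {
    k <- max(1L, round(smooth_ms / (t[2] - t[1])))
    if (k %% 2 == 0) k <- k + 1L
    if (k > 1 && k < length(v)) {
      sm <- stats::filter(v, rep(1 / k, k), sides = 2)
      pad <- (k - 1L) / 2L
      sm[seq_len(pad)] <- v[seq_len(pad)]
      sm[(length(v) - pad + 1L):length(v)] <- v[(length(v) - pad + 1L):length(v)]
      v <- as.numeric(sm)
    }
  }
  sel <- .window_sel(trace, window)
  if (is.null(window)) {
    up <- which(v > 0)[1]
    if (!is.na(up)) sel <- sel & seq_along(t) > up
  }
  empty <- data.frame(takeoff_time = numeric(0), takeoff_voltage = numeric(0),
                      peak_time = numeric(0), peak_voltage = numeric(0),
                      amplitude = numeric(0))
  idx <- which(sel)
  if (length(idx) < 5) return(empty)
  tv <- t[idx]; vv <- v[idx]
  ex <- .extrema(vv, thr = min_amplitude)
  if (!length(ex$idx)) return(empty)
  out <- empty
  mins <- which(ex$kind == -1L)
  for (k in mins) {
    if (k == length(ex$idx)) next           # no subsequent maximum
    i_min <- ex$idx[k]; i_max <- ex$idx[k + 1L]
    if (vv[i_min] < band[1] || vv[i_min] > band[2]) next
    amp <- vv[i_max] - vv[i_min]
    if (amp < min_amplitude) next
    if (tv[i_max] - tv[i_min] < min_duration) next
    out <- rbind(out, data.frame(
      takeoff_time = tv[i_min], takeoff_voltage = vv[i_min],
      peak_time = tv[i_max], peak_voltage = vv[i_max], amplitude = amp))
  }
  out[order(out$takeoff_time), , drop = FALSE]
}

#' Count oscillation cycles of a signal
#'
#' Counts local maxima whose prominence exceeds `prominence_frac` times the
#' signal's range over the window (with an absolute floor), excluding the
#' primary stimulus-evoked transient: when no window is given, counting
#' starts at the first post-upstroke minimum.
#'
#' @param trace a trace.
#' @param signal trace column name (e.g. `"V_m_mV"`, `"Ca_sub_mM"`).
#' @param window numeric `c(t_on, t_off)` or `NULL`.
#' @param prominence_frac prominence threshold as a fraction of the range.
#' @param min_prominence absolute prominence floor in signal units; default
#'   0.5 mV for voltage signals, 1e-5 mM for concentrations, 0 otherwise.
#' @return An `oscillation_report` list: `n_cycles`, `peak_times`,
#'   `trough_times`, `mean_amplitude`.
#' @export
detect_oscillations <- function(trace, signal = "V_m_mV", window = NULL,
                                prominence_frac = 0.05,
                                min_prominence = NULL) {
  if (!signal %in% names(trace)) stop("unknown signal: ", signal)
  if (is.null(min_prominence))
    min_prominence <- if (grepl("mV$", signal)) 0.5
                      else if (grepl("mM$", signal)) 1e-5 else 0
  t <- trace$t_ms
  x <- trace[[signal]]
  sel <- .window_sel(trace, window)
  if (is.null(window)) {
    # start at the first post-upstroke minimum of the signal
    v <- trace$V_m_mV
    up <- which(v > 0)[1]
    if (!is.na(up)) {
      after <- which(seq_along(t) > up)
      ex0 <- .extrema(x[after], thr = 0)
      m0 <- ex0$idx[ex0$kind == -1L][1]
      if (!is.na(m0)) sel <- sel & seq_along(t) >= after[m0]
    }
  }
  tv <- t[sel]; xv <- x[sel]
  rep0 <- structure(list(n_cycles = 0L, peak_times = numeric(0),
                         trough_times = numeric(0),
                         mean_amplitude = NA_real_, signal = signal),
                    class = "oscillation_report")
  if (length(xv) < 5) return(rep0)
  thr <- max(prominence_frac * diff(range(xv)), min_prominence)
  ex <- .extrema(xv, thr = thr)
  pk <- ex$idx[ex$kind == 1L]
  tr <- ex$idx[ex$kind == -1L]
  if (!length(pk)) return(rep0)
  amp <- if (length(ex$idx) >= 2) mean(abs(diff(xv[ex$idx]))) else NA_real_
  structure(list(n_cycles = length(pk), peak_times = tv[pk],
                 trough_times = tv[tr], mean_amplitude = amp,
                 signal = signal),
            class = "oscillation_report")
}

#' @export
print.oscillation_report <- function(x, ...) {
  cat(sprintf("<oscillation_report> %s: %d cycle(s), mean amplitude %s\n",
              x$signal, x$n_cycles, format(signif(x$mean_amplitude, 3))))
  invisible(x)
}

#' Phase relation between V_m and Ca_sub oscillations
#'
#' Pairs each V_m turning point (maxima with maxima, minima with minima)
#' with the nearest Ca turning point and averages the signed lag
#' (positive = V_m leads, i.e. the V_m turning point occurs earlier).
#' The label is `in_phase` when |lag| < 10% of the mean cycle period,
#' `out_of_phase` when |lag| > 40% of the period, otherwise `vm_leads`
#' or `ca_leads` by the sign of the lag.
#'
#' @param trace a trace with `V_m_mV` and `Ca_sub_mM` columns.
#' @param window numeric `c(t_on, t_off)` or `NULL`.
#' @param ca_signal name of the Ca column.
#' @param ... passed to [detect_oscillations()].
#' @return A `phase_relation` list: `label`, `lag_ms`, `period_ms`,
#'   `n_pairs`.
#' @export
phase_relation <- function(trace, window = NULL, ca_signal = "Ca_sub_mM",
                           ...) {
  ov <- detect_oscillations(trace, "V_m_mV", window, ...)
  oc <- detect_oscillations(trace, ca_signal, window, ...)
  if (ov$n_cycles < 2 || oc$n_cycles < 2)
    stop("insufficient oscillation: need at least 2 cycles in both signals")
  pair_lag <- function(tv, tc) {
    if (!length(tv) || !length(tc)) return(numeric(0))
    vapply(tv, function(ti) tc[which.min(abs(tc - ti))] - ti, 0)
  }
  lags <- c(pair_lag(ov$peak_times, oc$peak_times),
            pair_lag(ov$trough_times, oc$trough_times))
  period <- mean(diff(sort(ov$peak_times)))
  # circular average so lags near +/- half a period do not cancel
  th <- 2 * pi * lags / period
  lag <- period * atan2(mean(sin(th)), mean(cos(th))) / (2 * pi)
  frac <- abs(lag) / period
  label <- if (frac < 0.10) "in_phase"
           else if (frac > 0.40) "out_of_phase"
           else if (lag > 0) "vm_leads" else "ca_leads"
  structure(list(label = label, lag_ms = lag, period_ms = period,
                 n_pairs = length(lags)),
            class = "phase_relation")
}

#' @export
print.phase_relation <- function(x, ...) {
  cat(sprintf("<phase_relation> %s (lag %.1f ms, period %.1f ms, %d pairs)\n",
              x$label, x$lag_ms, x$period_ms, x$n_pairs))
  invisible(x)
}
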