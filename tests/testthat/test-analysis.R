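# APD measurement, EAD detection, oscillation counting, phase relations.

# rectangular pseudo-AP: rest, a plateau of width w, rest
rect_trace <- function(w, level = 0, rest = -85, t_end = 600, t_up = 100) {
  t <- seq(0, t_end)
  v <- ifelse(t >= t_up & t < t_up + w, level, rest)
  structure(data.frame(t_ms = t, V_m_mV = v, Ca_sub_mM = 1e-4),
            class = c("wg_trace", "data.frame"))
}

test_that("APD of a rectangular pulse equals its width", {
  for (w in c(50, 120, 300)) {
    apd <- measure_apd(rect_trace(w))
    expect_true(apd$repolarized)
    expect_equal(apd$APD, w, tolerance = 1e-8)
  }
  # no downward crossing -> not repolarized
  apd <- measure_apd(rect_trace(1000, t_end = 600))
  expect_false(apd$repolarized)
  expect_true(is.na(apd$APD))
  # no upstroke at all
  expect_error(measure_apd(rect_trace(0)), "upstroke")
})

test_that("EAD detection finds constructed humps at their minima", {
  for (k in c(1, 2, 4)) {
    spec <- synthetic_trace_spec(n_humps = k, hump_amp_vm = 12, noise_sd = 0)
    tr <- generate_synthetic_trace(spec)
    ev <- detect_eads(tr)
    expect_equal(nrow(ev), k)
    ref <- attr(tr, "hump_takeoffs")
    expect_true(all(abs(ev$takeoff_time - ref) < 0.25 * spec$period))
    expect_true(all(ev$amplitude > 0))
    expect_true(all(ev$takeoff_time < ev$peak_time))
  }
})

test_that("a monotonically repolarizing AP yields no events", {
  tr <- generate_synthetic_trace(synthetic_trace_spec(n_humps = 0))
  expect_equal(nrow(detect_eads(tr)), 0)
  expect_equal(nrow(detect_eads(control_ap())), 0)
})

test_that("detection is invariant to time shifts and small offsets", {
  tr <- generate_synthetic_trace(synthetic_trace_spec(n_humps = 3))
  ev <- detect_eads(tr)
  sh <- tr; sh$t_ms <- sh$t_ms + 500
  ev_sh <- detect_eads(sh)
  expect_equal(ev_sh$takeoff_time, ev$takeoff_time + 500)
  expect_equal(ev_sh$amplitude, ev$amplitude)
  # a vertical offset that keeps takeoffs inside the plateau band
  off <- tr; off$V_m_mV <- off$V_m_mV + 5
  ev_off <- detect_eads(off)
  expect_equal(ev_off$takeoff_time, ev$takeoff_time)
  expect_equal(ev_off$amplitude, ev$amplitude, tolerance = 1e-10)
})

test_that("detector sharpness: events iff amplitudes clear the threshold", {
  thr <- 1
  for (seed in 1:5) {
    # large humps with low noise: full recall, no false positives
    spec <- synthetic_trace_spec(n_humps = 3, hump_amp_vm = 14,
                                 noise_sd = 0, seed = seed, period = 180)
    tr <- generate_synthetic_trace(spec)
    ev <- detect_eads(tr, min_amplitude = thr)
    # every realized hump is at least 2x threshold by construction
    expect_equal(nrow(ev), 3)
    # tiny humps below half the threshold: nothing detected
    small <- synthetic_trace_spec(n_humps = 3, hump_amp_vm = 0.45,
                                  noise_sd = 0, seed = seed, period = 180)
    expect_equal(nrow(detect_eads(generate_synthetic_trace(small),
                                  min_amplitude = thr)), 0)
  }
})

test_that("oscillation counting matches constructed cycle counts", {
  t <- seq(0, 2000)
  flat <- data.frame(t_ms = t, x = rep(3, length(t)))
  expect_equal(detect_oscillations(flat, "x")$n_cycles, 0L)
  for (n in c(2, 5)) {
    per <- 2000 / n
    sine <- data.frame(t_ms = t,
                       x = sin(2 * pi * (t - per / 4) / per))
    rep <- detect_oscillations(sine, "x", window = c(0, 2000))
    expect_equal(rep$n_cycles, n)
    # peaks and troughs interleave
    both <- c(rep$peak_times, rep$trough_times)
    is_peak <- c(rep(TRUE, length(rep$peak_times)),
                 rep(FALSE, length(rep$trough_times)))[order(both)]
    expect_true(all(diff(is_peak) != 0))
  }
  expect_error(detect_oscillations(flat, "nope"), "unknown signal")
  expect_error(detect_oscillations(flat, "x", window = c(5000, 6000)),
               "outside")
})

test_that("phase relations recover constructed lags", {
  t <- seq(0, 2400)
  per <- 300
  mk <- function(lag) {
    structure(data.frame(
      t_ms = t,
      V_m_mV = -20 + 10 * sin(2 * pi * t / per),
      Ca_sub_mM = 1e-3 + 5e-4 * sin(2 * pi * (t - lag) / per)),
      class = c("wg_trace", "data.frame"))
  }
  pr0 <- phase_relation(mk(0))
  expect_equal(pr0$label, "in_phase")
  expect_lt(abs(pr0$lag_ms), 2)
  for (lag in c(60, 90)) {   # 20-30% of the period: a clear lead
    pr <- phase_relation(mk(lag))
    expect_equal(pr$lag_ms, lag, tolerance = 2)
    expect_equal(pr$label, "vm_leads")
  }
  pr_half <- phase_relation(mk(per / 2))
  expect_equal(pr_half$label, "out_of_phase")
  pr_neg <- phase_relation(mk(-75))
  expect_equal(pr_neg$label, "ca_leads")
  # phase_relation(x, x) is in_phase for any oscillatory x
  tr <- mk(0); tr$Ca_sub_mM <- tr$V_m_mV
  expect_equal(phase_relation(tr)$label, "in_phase")
  # fewer than 2 cycles is an error
  short <- mk(0)[t <= 200, ]
  expect_error(phase_relation(short), "insufficient")
})
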