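# Stimulation schedules and clamp directives.

test_that("stimulus schedules place pulses as specified", {
  s <- stim_single()
  expect_equal(stim_current(s, c(0, 0.5, 0.999)), c(40, 40, 40))
  expect_equal(stim_current(s, c(-0.1, 1, 5)), c(0, 0, 0))

  s11 <- stim_s1s1(interval = 3000, n_s1 = 3)
  expect_equal(s11$starts, c(0, 3000, 6000))
  s12 <- stim_s1s2(s1_interval = 1000, s2_interval = 2000, n_s1 = 3)
  # final inter-pulse gap equals the S2 interval
  expect_equal(diff(tail(s12$starts, 2)), 2000)
  expect_equal(s12$starts, c(0, 1000, 2000, 4000))

  expect_error(stim_s1s1(interval = 0.5), "exceed")
  expect_error(stim_single(amplitude = -1), "positive")
})

test_that("delivered charge equals amplitude x duration x pulse count", {
  for (proto in list(stim_single(), stim_s1s1(500, 4), stim_s1s2(400, 900, 2))) {
    t <- seq(0, max(proto$starts) + 100, by = 0.01)
    q <- sum(stim_current(proto, t)) * 0.01
    expect_equal(q, proto$amplitude * proto$duration * length(proto$starts),
                 tolerance = 0.02)
  }
})

test_that("clamp directives validate their inputs", {
  expect_error(clamp_constant("V_m", -10, c(100, 100)), "t_on < t_off")
  expect_error(make_ramp_clamp("I_CaL", takeoff_time = 50, end_value = 0,
                               window = c(100, 200)), "inside")
  tr <- data.frame(t_ms = 0:100, Ca_sub_mM = rep(1e-3, 101))
  expect_error(make_scaled_trace_clamp("Ca_sub", tr, scale = -1,
                                       window = c(0, 50)), "non-negative")
  expect_error(make_scaled_trace_clamp("Ca_sub", tr, scale = 1,
                                       window = c(150, 200)), "cover")
  expect_error(make_scaled_trace_clamp("Ca_sub", tr, signal = "bogus",
                                       window = c(0, 50)), "unknown signal")
})

test_that("clamp levels come from the extrema of the windowed signal", {
  tr <- data.frame(t_ms = seq(0, 1000),
                   x = 2 + sin(2 * pi * seq(0, 1000) / 200))
  lv <- clamp_levels_from_trace(tr, "x", c(0, 1000))
  expect_equal(unname(lv), c(1, 3), tolerance = 1e-3)
  const <- data.frame(t_ms = 0:10, x = rep(7, 11))
  expect_equal(unname(clamp_levels_from_trace(const, "x", c(0, 10))), c(7, 7))
  expect_error(clamp_levels_from_trace(tr, "x", c(2000, 3000)), "empty")
})

test_that("a clamp never modifies the trajectory before its window", {
  p <- wg_params()
  free <- simulate_ap(p, stim_single(), t_end = 400)
  cl <- clamp_constant("Ca_sub", 5e-4, c(200, 400))
  clamped <- simulate_ap(p, stim_single(), clamps = list(cl), t_end = 400)
  pre <- free$t_ms < 200
  expect_identical(free$V_m_mV[pre], clamped$V_m_mV[pre])
  expect_identical(free$Ca_sub_mM[pre], clamped$Ca_sub_mM[pre])
  # inside the window the target is held
  inside <- clamped$t_ms > 200 & clamped$t_ms < 400
  expect_true(all(abs(clamped$Ca_sub_mM[inside] - 5e-4) < 1e-12))
})

test_that("duplicate targets and scale-1 self-clamps behave as specified", {
  p <- wg_params()
  expect_error(
    simulate_ap(p, stim_single(), t_end = 100,
                clamps = list(clamp_constant("V_m", -10, c(0, 50)),
                              clamp_constant("V_m", 0, c(50, 100)))),
    "one clamp")
  # clamping Ca_sub to 1.0 x its own free trace (from the plateau onward,
  # after the release episode, where the two submembrane compartments agree)
  # reproduces the free V_m
  free <- simulate_ap(p, stim_single(), t_end = 400)
  cl <- make_scaled_trace_clamp("Ca_sub", free, "Ca_sub_mM", 1, c(250, 400))
  self <- simulate_ap(p, stim_single(), clamps = list(cl), t_end = 400)
  expect_lt(max(abs(free$V_m_mV - self$V_m_mV)), 2)
  # scale 0 holds Ca at the positivity floor and stays finite
  cl0 <- make_scaled_trace_clamp("Ca_sub", free, "Ca_sub_mM", 0, c(250, 400))
  z <- simulate_ap(p, stim_single(), clamps = list(cl0), t_end = 400)
  expect_false(attr(z, "diverged"))
  expect_true(all(is.finite(z$V_m_mV)))
})

test_that("a zero-slope current ramp equals a constant clamp from takeoff", {
  p <- wg_params(alpha = c(P_Ca = 2))
  base <- simulate_ap(p, stim_single(), t_end = 400)
  i0 <- base$I_CaL_AF[base$t_ms == 150]
  ramp <- make_ramp_clamp("I_CaL", takeoff_time = 150, end_value = i0,
                          window = c(150, 400))
  cst <- clamp_constant("I_CaL", NA_real_, c(150, 400))
  a <- simulate_ap(p, stim_single(), clamps = list(ramp), t_end = 400)
  b <- simulate_ap(p, stim_single(), clamps = list(cst), t_end = 400)
  expect_lt(max(abs(a$V_m_mV - b$V_m_mV)), 0.5)
})

test_that("default clamp onset tracks the first EAD takeoff or the plateau", {
  tr <- control_ap()
  on <- ead_phase_onset(tr)
  # no EADs in the control AP: onset is where V_m first falls below +20 mV
  expect_true(is.finite(on))
  expect_lt(tr$V_m_mV[which(tr$t_ms == on)], 20)
  syn <- generate_synthetic_trace(synthetic_trace_spec(n_humps = 2))
  expect_equal(ead_phase_onset(syn),
               detect_eads(syn)$takeoff_time[1])
})
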