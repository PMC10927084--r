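# Model parameters, scaling, derivatives, integrator.

test_that("scaling factors multiply control values and cannot stack", {
  p0 <- wg_params()
  # identity
  p1 <- apply_scaling(p0, c(k_max = 1, P_Ca = 1))
  expect_identical(p1$values, p0$values)
  # forced arithmetic at the dissection points
  p2 <- wg_params(alpha = c(P_Ca = 5.4))
  expect_equal(p2$values[["P_Ca"]], 5.4 * 0.00027)
  p3 <- wg_params(alpha = c(G_Ks = 0.56))
  expect_equal(p3$values[["G_Ks"]], 0.56 * 1.23)
  # a derived set carries a flag; applying scaling twice is an error
  expect_true(p2$scaled)
  expect_error(apply_scaling(p2, c(P_Ca = 2)), "once")
  # invalid inputs
  expect_error(apply_scaling(p0, c(P_Ca = -1)), "non-negative")
  expect_error(apply_scaling(p0, c(G_Na = 2)), "alpha names")
  expect_error(apply_scaling(p0, 2), "named")
})

test_that("control constants carry their stated values", {
  v <- wg_params()$values
  expect_equal(v[["k_max"]], 0.2)
  expect_equal(v[["J_Caslmyo"]], 7.4485e-13)
  expect_equal(v[["P_Ca"]], 0.00027)
  expect_equal(v[["G_Ks"]], 1.23)
  expect_equal(v[["I_NCX_bar"]], 5)
})

test_that("the frozen rest state is a fixed point of the dynamics", {
  st <- wg_initial_state()
  d <- wg_derivatives(st, wg_params())
  # everything quiescent in native units (mV/ms, 1/ms, mM/ms)
  expect_lt(max(abs(d$deriv)), 1e-6)
  # RyR occupancies sum to 1
  expect_equal(sum(st[c("ryr_r", "ryr_o", "ryr_i")]) +
                 (1 - sum(st[c("ryr_r", "ryr_o", "ryr_i")])), 1)
})

test_that("derivative evaluation honors clamps and conservation identities", {
  st <- wg_initial_state()
  p <- wg_params()
  # Ca_sub clamp zeroes both submembrane Ca derivatives exactly
  cl <- clamp_constant("Ca_sub", 5e-4, c(0, 100))
  d <- wg_derivatives(st, p, clamps = list(cl), t = 10)
  expect_identical(unname(d$deriv[c("Ca_jxn", "Ca_sl")]), c(0, 0))
  # outside its window the clamp is inert
  d2 <- wg_derivatives(st, p, clamps = list(cl), t = 200)
  d0 <- wg_derivatives(st, p)
  expect_identical(d2$deriv, d0$deriv)
  # dV/dt equals -(sum of current components) + I_sti
  st2 <- st; st2[["V_m"]] <- -20; st2[["d"]] <- 0.3
  d3 <- wg_derivatives(st2, p, I_sti = 40)
  expect_equal(d3$I_ion, sum(d3$currents), tolerance = 1e-12)
  expect_equal(unname(d3$deriv[["V_m"]]), -sum(d3$currents) + 40,
               tolerance = 1e-10)
  # non-finite state is rejected
  st_bad <- st; st_bad[["V_m"]] <- NaN
  expect_error(wg_derivatives(st_bad, p), "non-finite")
  # unknown clamp target is rejected at construction
  expect_error(clamp_constant("I_Ks", 1, c(0, 10)), "arg")
})

test_that("a quiescent simulation stays at rest", {
  tr <- simulate_ap(wg_params(), stim_none(), t_end = 2000)
  expect_lt(diff(range(tr$V_m_mV)), 1)
  expect_false(attr(tr, "diverged"))
})

test_that("the control AP repolarizes without afterdepolarizations", {
  tr <- control_ap()
  apd <- measure_apd(tr)
  expect_true(apd$repolarized)
  expect_gt(apd$APD, 100)
  expect_lt(apd$APD, 500)
  expect_gt(max(tr$V_m_mV), 20)           # overshoot
  expect_equal(nrow(detect_eads(tr)), 0)
})

test_that("integration is deterministic and step-halving converges", {
  a <- simulate_ap(wg_params(), stim_single(), t_end = 400)
  b <- simulate_ap(wg_params(), stim_single(), t_end = 400)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # explicit Euler at dt = 0.01 vs 0.005 ms on the same 1 ms storage grid
  h <- simulate_ap(wg_params(), stim_single(), t_end = 400,
                   dt = 0.005, stride = 200)
  expect_equal(a$t_ms, h$t_ms)
  expect_lt(max(abs(a$V_m_mV - h$V_m_mV)), 0.5)
})

test_that("gating variables stay inside [0, 1] along trajectories", {
  gate_names <- c("m", "h", "j", "d", "f", "fCaB_jxn", "fCaB_sl",
                  "x_to", "y_to", "x_kr", "x_ks",
                  "ryr_r", "ryr_o", "ryr_i")
  for (alpha in list(NULL, alpha_points$typeI, alpha_points$typeIV)) {
    p <- if (is.null(alpha)) wg_params() else wg_params(alpha = alpha)
    st <- wg_initial_state()
    # checkpoints every 25 ms across the AP
    for (k in 1:16) {
      tr <- simulate_ap(p, if (k == 1) stim_single() else stim_none(),
                        t_end = 25, init = st, stride = 2500)
      st <- attr(tr, "final_state")
      g <- st[gate_names]
      expect_true(all(g >= 0 & g <= 1))
      expect_true(all(st[c("Ca_jxn", "Ca_sl", "Ca_i", "Ca_jsr",
                           "Ca_nsr")] >= 0))
    }
  }
})

test_that("total Ca is conserved when transmembrane Ca fluxes are blocked", {
  p <- wg_params(overrides = list(block_ca_transmembrane = 1))
  st <- wg_initial_state()
  m0 <- wg_total_ca(st)
  tr <- simulate_ap(p, stim_single(), t_end = 5000, init = st,
                    stride = 10000)
  m1 <- wg_total_ca(attr(tr, "final_state"))
  expect_lt(abs(m1 - m0) / m0, 1e-3)
})

test_that("submembrane compartments equilibrate outside release episodes", {
  tr <- control_ap()
  # after the SR release episode the cleft-to-subsarcolemmal difference is
  # negligible on the scale of the submembrane transient (they are treated
  # as the single pool [Ca]_sub); during release the cleft leads by design
  late <- tr$t_ms >= 600
  gap <- abs(tr$Ca_jxn_mM[late] - tr$Ca_sl_mM[late])
  expect_lt(max(gap) / max(tr$Ca_sub_mM), 0.02)
})

test_that("numerical blow-up is signalled with the failure time", {
  # a grossly depolarized, Na-flooded start diverges under Euler
  st <- wg_initial_state()
  st[["V_m"]] <- 450
  expect_error(
    simulate_ap(wg_params(), stim_single(amplitude = 1e4, duration = 50),
                t_end = 100, init = st),
    "divergence at t")
  tr <- simulate_ap(wg_params(), stim_single(amplitude = 1e4, duration = 50),
                    t_end = 100, init = st, on_divergence = "keep")
  expect_true(attr(tr, "diverged"))
  expect_true(is.finite(attr(tr, "t_diverged")))
})
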