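# Flattened inactivation curve and steady-state characterization protocols.

test_that("flatten_fss clamps the curve at its minimum beyond the argmin", {
  cv <- fss_curve("original")
  fl <- flatten_fss(cv)
  # brute-force check of the rule
  k <- which.min(cv$f_ss)
  expect_identical(fl$f_ss[seq_len(k)], cv$f_ss[seq_len(k)])
  expect_true(all(fl$f_ss[k:nrow(fl)] == cv$f_ss[k]))
  # non-increasing and bounded
  expect_true(all(diff(fl$f_ss) <= 1e-12))
  expect_true(all(fl$f_ss >= 0 & fl$f_ss <= 1))
  # idempotent
  expect_identical(flatten_fss(fl)$f_ss, fl$f_ss)
  # identity on an already non-increasing curve
  mono <- data.frame(V_m_mV = -50:50,
                     f_ss = rev(seq(0.01, 1, length.out = 101)))
  expect_identical(flatten_fss(mono)$f_ss, mono$f_ss)
  expect_error(flatten_fss(data.frame(V_m_mV = c(2, 1), f_ss = c(0.5, 0.4))),
               "increasing")
})

test_that("the model's flattened variant equals the tabulated rule", {
  v <- seq(-90, 70, by = 0.25)
  flat_model <- fss_curve("flattened", v = v)
  flat_rule <- flatten_fss(fss_curve("original", v = v))
  # the argmin of the model is located on a finer internal grid, so allow
  # one tabulation step of slack at the kink
  expect_lt(max(abs(flat_model$f_ss - flat_rule$f_ss)), 1e-3)
  # the original curve is genuinely non-monotonic (late rise)
  orig <- fss_curve("original", v = v)
  expect_gt(orig$f_ss[length(v)], min(orig$f_ss) + 0.2)
})

test_that("peak L-type current falls monotonically with clamped Ca_sub", {
  tb <- peak_ical_vs_casub(holding_vms = c(-20, 0, 20),
                           casub_levels = c(1e-4, 1e-3, 5e-3, 2e-2))
  for (vm in unique(tb$holding_Vm_mV)) {
    s <- tb[tb$holding_Vm_mV == vm, ]
    s <- s[order(s$Ca_sub_mM), ]
    expect_true(all(diff(s$peak_ICaL_AF) < 0))
  }
  # identical levels give identical peaks
  tb2 <- peak_ical_vs_casub(0, c(1e-3, 1e-3))
  expect_equal(tb2$peak_ICaL_AF[1], tb2$peak_ICaL_AF[2])
  # saturating Ca: the peak collapses toward zero
  hi <- peak_ical_vs_casub(0, c(1e-4, 0.5))
  expect_lt(hi$peak_ICaL_AF[2], 0.15 * hi$peak_ICaL_AF[1])
  expect_error(peak_ical_vs_casub(0, c(-1e-3)), "positive")
})

test_that("the Ca_sub-holding-V relation is non-monotonic and the flattened
          curve removes the second rise", {
  lv <- c(-40, -25, 0, 10, 30)
  tb <- casub_vs_holding_vm(lv, variant = "zero_NCX", hold_ms = 8000)
  ca <- tb$Ca_sub_mM
  # decrease / increase / decrease triple (window-current peak, trough,
  # late-rise bump, final fall)
  expect_gt(ca[2], ca[3])        # falls past the window-current peak
  expect_gt(ca[4], ca[3])        # second rise from the elevated late f_ss
  expect_gt(ca[4], ca[5])        # decreases again at high voltages
  # flattening removes the second rise: monotone decay beyond the peak
  p_flat <- wg_params(fss = "flattened")
  tf <- casub_vs_holding_vm(lv, variant = "zero_NCX", params = p_flat,
                            hold_ms = 8000)
  k <- which.max(tf$Ca_sub_mM)
  expect_true(all(diff(tf$Ca_sub_mM[k:length(lv)]) <= 1e-6))
})

test_that("zeroing currents via the variant equals zeroing via parameters", {
  lv <- c(-70, -20)
  a <- casub_vs_holding_vm(lv, variant = "zero_NCX", hold_ms = 3000)
  p0 <- wg_params(alpha = c(I_NCX_bar = 0))
  b <- casub_vs_holding_vm(lv, variant = "full", params = p0, hold_ms = 3000)
  expect_equal(a$Ca_sub_mM, b$Ca_sub_mM, tolerance = 1e-10)
  # no trigger and no window current: Ca stays near the diastolic level
  z <- casub_vs_holding_vm(-70, variant = "zero_ICaL", hold_ms = 3000)
  expect_lt(z$Ca_sub_mM, 3e-4)
  expect_error(casub_vs_holding_vm(100), "within")
})
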