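# Shared fixtures, computed once per test run.

fixture_env <- new.env()

# short control AP (1 s), reused across analysis tests
control_ap <- function() {
  if (is.null(fixture_env$control_ap))
    fixture_env$control_ap <- simulate_ap(wg_params(), stim_single(),
                                          t_end = 1000)
  fixture_env$control_ap
}

# representative scaling-factor sets from the clamp-dissection experiments
alpha_points <- list(
  typeI   = c(k_max = 2, J_Caslmyo = 2.64, I_NCX_bar = 1,
              G_Ks = 1.16, P_Ca = 5.4),
  typeII  = c(k_max = 7, J_Caslmyo = 3.6, I_NCX_bar = 2.2,
              G_Ks = 0.56, P_Ca = 2.8),
  typeIII = c(k_max = 2, J_Caslmyo = 2.64, I_NCX_bar = 1,
              G_Ks = 1.6, P_Ca = 8.2),
  typeIV  = c(k_max = 7, J_Caslmyo = 1, I_NCX_bar = 1.2,
              G_Ks = 1, P_Ca = 1))

classify_cached <- function(name, fss = "original", ...) {
  key <- paste0("cls_", name, "_", fss)
  if (is.null(fixture_env[[key]])) {
    params <- if (name == "control") wg_params(fss = fss)
              else wg_params(alpha = alpha_points[[name]], fss = fss)
    fixture_env[[key]] <- classify_ead_mechanism(params, ...)
  }
  fixture_env[[key]]
}
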