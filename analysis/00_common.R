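# Shared setup for the analysis drivers: output location and the four
# representative scaling-factor sets from the clamp-dissection experiments.
library(eadissect)

results_dir <- file.path("results")
dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)

alpha_points <- list(
  typeI   = c(k_max = 2, J_Caslmyo = 2.64, I_NCX_bar = 1,
              G_Ks = 1.16, P_Ca = 5.4),
  typeII  = c(k_max = 7, J_Caslmyo = 3.6, I_NCX_bar = 2.2,
              G_Ks = 0.56, P_Ca = 2.8),
  typeIII = c(k_max = 2, J_Caslmyo = 2.64, I_NCX_bar = 1,
              G_Ks = 1.6, P_Ca = 8.2),
  typeIV  = c(k_max = 7, J_Caslmyo = 1, I_NCX_bar = 1.2,
              G_Ks = 1, P_Ca = 1))
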