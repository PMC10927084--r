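# Coarse phase diagram in the alpha(P_Ca) x alpha(G_Ks) plane on the
# background of the voltage-driven-EAD experiments (alpha(k_max) = 2,
# alpha(J_Caslmyo) = 2.64, alpha(I_NCX) = 1).
#
# An 11 x 9 grid takes roughly ten minutes single-threaded; the resolution
# is a deliberate desk-scale choice.  Writes: phase_diagram.csv.
source(file.path("analysis", "00_common.R"))

grid <- phase_diagram(
  alpha_PCa = c(0.5, 1, 2, 3, 4, 5, 5.4, 6.5, 8.2, 9, 10),
  alpha_GKs = c(0.2, 0.4, 0.56, 0.8, 1, 1.16, 1.6, 2.2, 3),
  background = c(k_max = 2, J_Caslmyo = 2.64, I_NCX_bar = 1),
  with_confirmatory = FALSE)
print(table(grid$label))
write.csv(grid, file.path(results_dir, "phase_diagram.csv"),
          row.names = FALSE)
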