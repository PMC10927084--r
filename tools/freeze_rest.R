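# Regenerates the frozen control resting state in R/rest_state.R.
# Run from the package root after installing the current build.
library(eadissect)
eq <- simulate_ap(wg_params(), stim_none(), t_end = 60000,
                  init = eadissect:::.wg_seed_state(), stride = 2000)
fs <- attr(eq, "final_state")
cat(paste(sprintf("%.10g", fs), collapse = ", "), "\n")
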