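# Frozen control resting state (unstimulated equilibration to the quiescent
# steady state at control parameters, explicit Euler dt = 0.01 ms; 60 s,
# max |d/dt| < 1e-6 in native units).  Regenerated by tools/freeze_rest.R
# after any change to the control constants.
.wg_rest_values <- c(
  -86.44378246, 0.001214481486, 0.9890610588, 0.9929592394, 6.202013145e-06,
  1, 0.01336574019, 0.01146281092, 0.0003001103331, 0.9999984677,
  0.007697203468, 0.00513719666, 0.9485936475, 4.140570131e-08,
  2.243863088e-09, 0.0001240093164, 0.0001061502374, 9.793086257e-05,
  0.6755456053, 0.6766184585)
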