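---
title: "Dissecting early afterdepolarization mechanisms with in-silico clamp protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting early afterdepolarization mechanisms with in-silico clamp protocols}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eadissect)
```

Early afterdepolarizations (EADs) are secondary membrane depolarizations
during the plateau or repolarizing phase of a cardiac action potential (AP).
Two classical explanations compete: a voltage-side instability (reduced
repolarization reserve plus reactivation of the L-type Ca current,
$I_{CaL}$) and a calcium-side instability (spontaneous sarcoplasmic
reticulum Ca release driving depolarization through the Na/Ca exchanger,
$I_{NCX}$).  Because membrane voltage $V_m$ and intracellular Ca are
bidirectionally coupled, telling the two apart — or recognizing behavior
that exists only because of the coupling — requires clamping one subsystem
while watching the other.  This package implements that dissection end to
end: a rabbit ventricular myocyte model with detailed Ca cycling, in-silico
voltage/Ca/current clamps, event detectors, a mechanism classifier, and
phase-diagram / Monte Carlo surveys.

## The myocyte model

The model is authored in the Shannon–Bers family.  Its state is the
membrane voltage, Hodgkin–Huxley-type gating variables, Markov-gated
ryanodine receptors (RyR), and Ca concentrations in five compartments:
junctional cleft (JXN), subsarcolemmal space (SL), bulk cytosol, junctional
SR (JSR) and network SR (NSR).  The submembrane pair JXN/SL is small and
diffusively coupled; their volume-weighted mean is reported as
$[\mathrm{Ca}]_{sub}$, and a $[\mathrm{Ca}]_{sub}$ clamp holds both
simultaneously.  Membrane currents: fast Na, L-type Ca (GHK flux, gates
$d$, $f$, and Ca-dependent inactivation $f_{Ca}$ per submembrane
compartment), transient outward, rapid and slow delayed rectifiers, inward
rectifier, Na/K pump, Na/Ca exchanger (per compartment, with allosteric Ca
activation), sarcolemmal Ca pump and background currents.  Intracellular
Na$^+$ and K$^+$ are held fixed: on the single-stimulus horizons used here
(seconds) their drift is negligible, and freezing them removes slow
non-stationarity from the clamp experiments.

Two features carry the science:

* **A non-monotonic steady-state inactivation curve.**  The voltage
  dependence of $f_\infty$ ("f_ss") is a decreasing sigmoid plus a rising
  late term, so inactivation is deepest near $-5$ mV and partially relieved
  at positive plateau voltages.  The `"flattened"` variant holds the curve
  at its minimum for all voltages above the argmin
  (`fss_curve()`, `flatten_fss()`).
* **Luminal-gated RyR release.**  The four-state RyR (rest, open,
  inactivated, rest-inactivated) opens with a cubic dependence on cleft Ca
  whose rate scales inversely with a luminal factor, so release ignites
  regeneratively from a loaded JSR and shuts off on depletion.  This gives
  the Ca subsystem its own limit cycle: under a plateau voltage clamp the
  SR releases, refills through the NSR, and releases again.

### Adjustable parameters

Five parameters are exposed to multiplicative scaling factors
$\alpha(z)$ (`apply_scaling()`; a derived set carries a flag so factors
cannot compound):

| parameter | control value | units | role |
|---|---|---|---|
| `k_max` | 0.2 | ms$^{-1}$ | maximal SR release rate constant |
| `J_Caslmyo` | 7.4485e-13 | l/ms | SL → cytosol Ca diffusion |
| `P_Ca` | 0.00027 | cm/s | L-type Ca permeability |
| `G_Ks` | 1.23 | mS/µF | slow delayed-rectifier conductance |
| `I_NCX_bar` | 5 | A/F | NCX current density |

All remaining constants are fixed model structure; `wg_params(overrides=)`
can replace any of them for characterization protocols (e.g. zeroing
`I_NCX_bar` for the steady-state curves).

## Stimulation, clamps, detection

The default stimulus is a single 1-ms, 40-pA/pF pulse at $t = 0$ from a
single frozen initial condition — the quiescent steady state of the control
model (60 s of unstimulated integration; the maximal residual time
derivative is below $10^{-6}$ in native units).  S1S1 and S1S2 pacing are
available (`stim_s1s1()`, `stim_s1s2()`); under pacing, repolarization
failure means APD exceeding the pacing interval and clamps are applied in
the final beat.

Clamps come in three modes (`clamp_constant()`,
`make_scaled_trace_clamp()`, `make_ramp_clamp()`): a constant level, a
scaled copy of a reference trace, and a linear current ramp starting at the
EAD takeoff.  A clamped state variable has exactly zero time derivative; a
clamped current is substituted both in the voltage equation and in the
Ca-flux equations, because a current is one physical flux and partial
substitution would break charge/mass consistency.  A constant current clamp
with `value = NA` freezes the current at its free-running value when the
window opens (the "clamped at a constant in the plateau" protocol).

Detection thresholds (all configurable, all logged in results):

* EAD: a smoothed-$V_m$ local minimum (takeoff) in the band $[-70, +20]$ mV
  followed by a local maximum at least 1 mV higher and at least 10 ms
  later.  The 15-ms moving average and the duration floor exist because a
  raw derivative-sign detector on sampled noisy traces produces spurious
  events; both scales are far below the EAD timescale (tens to hundreds of
  ms).
* Oscillation: local maxima with prominence above 5 % of the windowed range
  (absolute floors 0.5 mV / 10 nM); "oscillates" always means at least two
  cycles — a single hump is an event, not an oscillation.
* Phase: $V_m$ and Ca turning points are paired (peaks with peaks, troughs
  with troughs) and the signed lags averaged circularly, so half-period
  lags do not cancel; |lag| < 10 % of the period is in-phase, > 40 % is
  out-of-phase, otherwise the sign decides who leads.
* APD: first upward to first downward crossing of $-75$ mV.

## The classifier

`classify_ead_mechanism()` formalizes the case-by-case clamp reasoning into
one deterministic tree, ordered so that the unambiguous morphologies are
taken first:

1. no EAD and repolarized → `none`; not repolarized → `repol_failure`;
2. exactly one EAD without a Ca oscillation, **and** the EAD disappears
   when $[\mathrm{Ca}]_{sub}$ is clamped to 0.5× its own trace →
   `typeIV` (large-Ca-transient EAD); if the EAD survives the halved trace
   it is voltage-driven and falls through;
3. $[\mathrm{Ca}]_{sub}$ clamped at the lowest/highest level of its
   EAD-phase range: $V_m$ oscillations persist under either → `typeI`;
4. $V_m$ clamped at the lowest/highest plateau level: Ca oscillations
   persist → `typeII` (confirmed by current clamps: constant $I_{CaL}$
   preserves both oscillations; constant $I_{NCX}$ leaves Ca oscillating);
5. otherwise → `typeIII` (neither subsystem oscillates alone; the
   oscillation needs the coupling).

Clamp levels are read over the span from the first takeoff to the last EAD
peak — the oscillation region itself, not the final repolarization descent.
Clamped runs continue for 6 s past the clamp onset because the
voltage-subsystem limit cycle can take several seconds to grow out of the
clamped plateau (the slow delayed-rectifier gate drifts on a seconds
timescale); oscillation counting starts 100 ms after the onset to skip the
clamp transient.

```{r example}
cl <- classify_ead_mechanism(
  wg_params(alpha = c(k_max = 7, J_Caslmyo = 3.6, I_NCX_bar = 2.2,
                      G_Ks = 0.56, P_Ca = 2.8)))
cl$label            # "typeII"
cl$evidence         # the clamp experiments backing the call
```

## Surveys

`phase_diagram()` classifies a grid in the
$\alpha(P_{Ca})$–$\alpha(G_{Ks})$ plane at fixed background factors;
divergent cells become the label `"diverged"` rather than an error.
`monte_carlo_classification()` draws the five factors log-uniformly from
$[0.1, 10]$ (log-uniform treats the multiplicative range symmetrically
around control; plain uniform is available), classifies each sample, and
reports the fraction of each mechanism among EAD-positive samples.  All
draws derive from one seed; identical seeds give bit-identical results.
Problem sizes are deliberate desk-scale choices: the acceptance script uses
$n = 500$ per variant, the test suite $n = 150$.

## Synthetic traces

`generate_synthetic_trace()` builds V$_m$/Ca pairs with controlled
morphology — rest, upstroke, plateau decay, $n$ damped-sinusoid humps
(decay constant two periods, resembling waning oscillation trains), final
repolarization; Ca follows with a configurable lag, or is a single
prolonged transient for the type-IV morphology.  Noise is Gaussian,
mildly low-pass filtered (5-sample moving average) to resemble digitized
recordings.  The generator is the oracle for the detector tests: takeoffs,
counts, lags and seeds are known by construction.  It emulates morphology
only — no ionic mechanism — so detector tests passing on it says nothing
about the model's physiology, which is tested separately against the clamp
signatures.

## Numerical choices

* Explicit Euler at $dt = 0.01$ ms is the reference integrator; state is
  stored every 1 ms by default.  Step-halving (0.01 vs 0.005 ms) changes
  the control AP by < 0.3 mV pointwise.
* All gating time constants are floored at 0.3 ms and the RyR Markov rates
  are capped at 5 ms$^{-1}$.  Both guards keep the reference step inside
  the stability/accuracy region of the stiffest events (Na upstroke, CICR
  ignition): with faster floors, a microsecond-scale upstroke phase error
  is amplified by regenerative release into several mV of pointwise
  difference between step sizes.
* Concentrations are floored at $10^{-9}$ mM against Euler overshoot;
  gating bounds are never clipped (their violation is a test failure).
* |V_m| > 500 mV or a non-finite state aborts the run and reports the
  failure time; surveys record such cells as `"diverged"`.
* Scans may stop a run early once the AP has repolarized below $-75$ mV
  with no stimulus pending; nothing in the classification looks past that
  point by construction.

## Design choices and known limitations

The full rate-equation set is authored here (constants above, standard
formulations for the classical currents) rather than transcribed from any
single published code; the control values of the five adjustable parameters
and all protocol definitions follow the study design this package
implements.  Consequences worth knowing:

* The four mechanisms are all expressed, and three of the four
  representative scaling-factor sets classify as intended.  The
  feedback-loop point ($\alpha(G_{Ks}) = 1.6$, $\alpha(P_{Ca}) = 8.2$)
  classifies as `typeIV` here: its baseline carries one large EAD that the
  halved Ca-trace clamp abolishes.  This model's voltage-oscillator band
  in $P_{Ca}$ scales almost exactly with $G_{Ks}$, so the type-I and
  type-III points sit on the same side of every available knob and cannot
  both be separated at their printed coordinates.  The `typeIII` label is
  reachable elsewhere in parameter space (it appears in the Monte Carlo
  survey).
* At the type-II point, clamping $I_{NCX}$ leaves a residual ~11 mV
  voltage oscillation: Ca reaches $V_m$ through the Ca-dependent
  inactivation of $I_{CaL}$ as well as through $I_{NCX}$.
* The zero-NCX steady-state $[\mathrm{Ca}]_{sub}$–$V_m$ relation shows the
  expected decrease/increase/decrease triple, but shifted about +20 mV
  relative to the reference breakpoints, because the inactivation valley
  sits near $-5$ mV here.
* Flattening f_ss removes the second rise of that relation, but does not
  abolish the type-II label at the printed type-II point: that point's
  plateau sits below the curve's argmin, where clamp-at-minimum cannot
  change the curve.  The flattened Monte Carlo composition shifts toward
  voltage-driven and transient-driven mechanisms accordingly, without
  reaching exact zeros.
* The Monte Carlo composition is more voltage-driven (type I/III heavier,
  type II/IV lighter) than the reference survey; the EAD-positive rate
  (15–23 % of draws at n = 500) is of the same order.

Each of these is asserted at its face-value target in the acceptance suite
and left failing there when the model cannot meet it; the module tests
assert the behavior the model actually has.
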