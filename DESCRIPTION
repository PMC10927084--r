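Package: eadissect
Title: Clamp-Protocol Dissection of Early Afterdepolarization Mechanisms in a
    Ventricular Myocyte Model with Detailed Calcium Cycling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a Shannon-Bers-family rabbit ventricular action
    potential model with a two-compartment submembrane space, junctional and
    network sarcoplasmic reticulum, Markov ryanodine-receptor gating and a
    non-monotonic voltage-dependent inactivation curve of the L-type calcium
    current.  Provides in-silico voltage, calcium and ionic-current clamp
    protocols, detectors for action potentials and early afterdepolarizations
    (EADs), a decision tree classifying EADs into four mechanistic types
    (voltage-driven oscillations, calcium-driven oscillations, a
    calcium-voltage feedback loop, and a large calcium transient),
    phase-diagram parameter scans, and Monte Carlo surveys of the mechanism
    composition, including a variant with the late rise of the inactivation
    curve flattened.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
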