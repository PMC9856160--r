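Package: optotheta
Title: Septo-Hippocampal Electrophysiology Analysis for Optogenetic
    Stimulation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for optogenetic septo-hippocampal
    electrophysiology sessions recorded under a pulsed light protocol.
    Implements sharp-wave ripple detection with an envelope z-score
    threshold, multitaper spectral estimation with Slepian tapers and
    per-band on/off contrasts, event-triggered sliding-sweeps unit
    analysis with interval-shuffle significance, spike-field and
    field-field coherence, pairwise phase consistency, CA1 layer
    inference from ripple-triggered laminar profiles, and
    frequency-domain Wiener-Granger causality from ordinary
    least-squares vector autoregressions.  A seeded synthetic-session
    generator emulates urethane-state recordings (slow, theta and gamma
    rhythms over a 1/f background, laminar sharp-wave ripples,
    theta-locked septal and hippocampal units, directional
    septo-hippocampal theta coupling) so every analysis can be validated
    against injected ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
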