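Package: csnsim
Title: Conductance-Based Network Model of Stimulus-Specific Combination
    Sensitivity
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Single-compartment Hodgkin-Huxley-type models of songbird HVC
    projection neurons and local interneurons, first-order kinetic AMPA and
    GABA-A synapses, and a layered delay-loop network in which temporally
    ordered stimulus pairs are transformed into selective burst responses of
    a combination-sensitive output neuron.  Post-inhibitory rebound is
    carried by a low-threshold T-type calcium current in
    Goldman-Hodgkin-Katz form and a two-component hyperpolarization-activated
    inward current.  The package provides stimulus protocol generators for
    paired, reversed, single and repeated pulse conditions, compilation of a
    declarative network description into one coupled ODE system with a
    compiled right-hand side, adaptive integration, spike and burst metrics,
    windowed quantification of rebound-related intrinsic currents, and
    experiment drivers for delay sweeps, conductance heatmaps,
    stimulus-robustness sweeps and one-at-a-time sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
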