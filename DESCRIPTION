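Package: electrocyte
Title: Conductance-Based Modelling of High-Frequency Electrocyte
    Excitability and Sodium-Entry Energetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the excitable, innervated posterior membrane of the
    Eigenmannia electrocyte as a Hodgkin-Huxley-type conductance model
    (transient and persistent Nav currents, a delayed-rectifier Kv current
    and a leak) driven either by injected current or by a nicotinic
    acetylcholine-receptor synapse described with Goldman-Hodgkin-Katz
    electrodiffusion.  Provides stimulus generators (pulsatile synaptic
    trains, steady background activation, current-clamp steps and ramps),
    a stiff-capable integrator with a compiled right-hand side, spike
    detection and firing-rate measurement, and per-action-potential
    sodium-entry budgets split by pathway (Nav versus AChR) as a proxy for
    Na+/K+-ATPase demand.  Protocol drivers cover maximal sodium
    conductance calibration across 200-600 Hz, firing-threshold searches,
    frequency-intensity curves, devil's-staircase entrainment scans,
    stimulus-regime cost tables, exponential cost-versus-frequency fits,
    and jamming-avoidance-response sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
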