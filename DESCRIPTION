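Package: thermogating
Title: Thermodynamic Analysis of Heat-Activated Ion Channel Gating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising temperature-gated ion channels
    (thermoTRPs) from whole-cell patch-clamp recordings acquired under
    infrared laser temperature jumps. Implements the two-state gating
    thermodynamics (equilibrium constant, open probability, free energy,
    midpoint and threshold temperatures, Q10), Arrhenius pipette-current
    thermometry with per-experiment calibration tables, a digital twin of the
    PID-controlled heating rig together with a generative model of whole-cell
    current sweeps, and the full analysis chain: steady-state current
    extraction, capacitance normalisation, modified-Boltzmann fitting with
    leak and conductivity correction, van't Hoff regression, and cohort
    aggregation with enthalpy-entropy compensation diagnostics. Ships presets
    for the insect heat receptor RpTRPA5B and the control channels rTRPV1 and
    dTRPA1-D.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
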