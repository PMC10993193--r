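# thermogating

Thermodynamic characterisation of heat-gated ion channels (thermoTRPs) from
whole-cell patch-clamp recordings acquired under infrared-laser temperature
jumps — for channel biophysicists who need the full chain from raw current
sweeps to activation enthalpy, entropy, midpoint temperature and Q10, and
for anyone who wants to stress-test that chain on synthetic data with a
known ground truth.

## The model

A heat-activated channel is treated as a two-state (closed/open) system:

    ln Keq(T) = −ΔH/(RT) + ΔS/R          van't Hoff relation
    Po(T)     = Keq/(1 + Keq)            open probability
    ΔG(T)     = ΔH − TΔS = −RT ln Keq    free energy of opening
    T0.5      = ΔH/ΔS                    midpoint (Po = 0.5)
    Q10(T)    = Keq(T+10)/Keq(T)         thermosensitivity

with ΔH in kcal/mol, ΔS in cal/(mol·K) and R = 1.987 cal/(mol·K). The
measured steady-state current density is modelled as a temperature-dependent
leak plus a conductivity-scaled channel term:

    |i|(T) = L·a_leak(T) + A·a_i(T)·Po(T),   a(T) = exp[(ΔH_cond/R)(1/T_ref − 1/T)]

Per cell, the package extracts end-of-pulse steady states, converts
open-pipette currents to temperatures through the Arrhenius calibration
T = [1/T0 − (R/Ea)·ln(I/I0)]⁻¹ (Ea = 3.84 kcal/mol), fits the Boltzmann
model above, corrects to open probability, and estimates (ΔH, ΔS) by
van't Hoff regression of ln Keq on 1/T; cohorts are aggregated with
enthalpy–entropy compensation diagnostics. A digital twin of the heating
rig — a PID-controlled first-order thermal plant (τ = 34.2 ms) plus a
generative cell model — synthesises complete recordings so every estimator
can be validated against known ground truth. Presets ship for the insect
heat receptor RpTRPA5B (ΔH = 72.6 kcal/mol, T0.5 = 58.6 °C) and the control
channels rTRPV1 (88.3, 51.6 °C) and dTRPA1-D (68.7, 53.5 °C).

See the vignette `vignettes/thermodynamic-gating-analysis.Rmd` for the
models, conventions and design choices in full.

## Worked example

Closed-form thermodynamics of the RpTRPA5B parameters:

```r
library(thermogating)
g <- gating_thermodynamics(delta_h = 72.6, t_half_c = 58.6)
g
#> Two-state gating thermodynamics
#>   dH    = 72.6 kcal/mol
#>   dS    = 218.8 cal/(mol K)
#>   T0.5  = 331.75 K (58.60 C)
#>   Q10   = 25.1 at T0.5
open_probability(g, celsius_to_kelvin(53))
#> [1] 0.1311271
```

A Q10 of 25 at the midpoint means the opening equilibrium shifts 25-fold
over a 10 °C rise — noxious-heat-receptor territory (non-thermosensitive
channels sit below ~3). At 53 °C about 13 % of channels are open: the
channel is just crossing its conventional activation threshold (Po = 0.1).

The full in-silico experiment — simulate a calibration run and an 8-cell
cohort at 2 % noise, then push every cell through the analysis chain:

```r
res <- run_pipeline(pipeline_config(preset = "RpTRPA5B", seeds = 1:8))
res$cohort
#> Cohort summary (n = 8 cells)
#>   dH   = 72.65 +/- 0.1 kcal/mol
#>   dS   = 219 +/- 0.32 cal/(mol K)
#>   T0.5 = 58.58 +/- 0.005 C, T0.1 = 52.10 C, Q10 = 25.2
#>   dH-dS compensation slope = 329.5 K
```

The pipeline recovers the generative ground truth (72.6 kcal/mol, 58.6 °C)
well within the measurement noise, and the compensation slope sits near the
midpoint temperature in Kelvin (331.75 K), as it must when all cells share
one activation process. Setting `out_dir` in the config writes per-cell
summaries, van't Hoff point tables, the calibration table and a
self-reproducing config beside the results. A command-line front end with
`run`, `simulate`, `calibrate`, `fit` and `report` subcommands is installed
at `inst/cli/thermogating.R`.

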