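---
title: "Thermodynamic analysis of heat-gated channel recordings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamic analysis of heat-gated channel recordings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermogating)
```

## The two-state gating model

thermoTRP channels open in response to temperature alone. The simplest
thermodynamic description treats the channel as a two-state (closed/open)
system whose equilibrium constant obeys the van't Hoff relation

$$\ln K_{eq}(T) \;=\; -\frac{\Delta H}{RT} + \frac{\Delta S}{R},$$

with activation enthalpy $\Delta H$ (kcal/mol), activation entropy
$\Delta S$ (cal/(mol·K)) and $R = 1.987$ cal/(mol·K). The open probability
is $P_o = K_{eq}/(1+K_{eq})$, the free energy of the transition is
$\Delta G(T) = \Delta H - T\Delta S = -RT\ln K_{eq}$, and three derived
quantities summarise a channel's heat response:

* the midpoint $T_{0.5} = \Delta H/\Delta S$ (in consistent units), where
  $P_o = 0.5$ and $\Delta G = 0$;
* the activation "threshold" $T_{0.1}$, the temperature at $P_o = 0.1$,
  obtained by inverting the model,
  $T(p) = \Delta H / (\Delta S - R\,\mathrm{logit}(p))$;
* the temperature coefficient
  $Q_{10}(T) = K_{eq}(T+10)/K_{eq}(T)
  = \exp\!\big(\tfrac{\Delta H}{R}\tfrac{10}{T(T+10)}\big)$, far above ~3
  for thermoTRPs.

**Sign convention.** We write $P_o = 1/(1+e^{\Delta G/RT})$ with
$\Delta G = \Delta H - T\Delta S$. With $\Delta H, \Delta S > 0$ (heat
activation) this makes $P_o$ strictly increasing in temperature and is the
only convention consistent with the van't Hoff relation above; a logistic
written with $e^{-\Delta G/RT}$ in the denominator, which sometimes appears
in print, would invert the temperature dependence. Enthalpies are stored in
kcal/mol and entropies in cal/(mol·K) because every published value in this
field is quoted that way; the factor of 1000 is applied exactly once, inside
the core thermodynamic functions.

**Presets.** Three parameter sets ship with the package, each specified by
the published ($\Delta H$, $T_{0.5}$) pair with $\Delta S$ derived as
$1000\,\Delta H/T_{0.5}$ (K): the insect heat receptor RpTRPA5B
(72.6 kcal/mol, 58.6 °C), rat TRPV1 (88.3 kcal/mol, 51.6 °C) and fruit-fly
TRPA1-D (68.7 kcal/mol, 53.5 °C). Deriving $\Delta S$ from the midpoint
keeps each preset internally consistent; quoting $\Delta S$ and $T_{0.5}$
independently at printed precision generally does not (rounding a cohort
mean entropy by 1 cal/(mol·K) moves the implied midpoint by more than 1 °C),
so the midpoint — the quantity read directly off the $P_o(T)$ curve — takes
priority.

## Pipette-current thermometry

During an infrared temperature jump the bath temperature at the pipette tip
is read from the ionic current through an *open* pipette: electrolyte
mobility follows an Arrhenius law, so

$$T = \Big[\frac{1}{T_0} - \frac{R}{E_a}\ln\frac{I}{I_0}\Big]^{-1},$$

with $T_0$, $I_0$ the room-temperature baseline and $E_a = 3.84$ kcal/mol
the effective activation energy of the CsCl/NaCl solution pair used on this
kind of rig. The relation is taken in reciprocal form — the only reading
that is dimensionally consistent (its bracket has units of 1/K). Conversion
is exactly invertible, is scale-invariant in current (pipette diameter drops
out of the ratio), and heating from 23.5 °C to 71.7 °C corresponds to a
current ratio of ≈2.49 — a useful guard against cal/kcal unit mistakes.

A calibration run reduces a series of open-pipette sweeps at increasing
laser command levels to a table of (command level, steady temperature,
current ratio). Conventions the package fixes (acquisition practice varies
and is rarely reported): $I_0$ is the mean over a baseline window of the
*first* sweep, and steady-state windows default to the final 50 ms of each
sweep.

## The instrument twin

No raw recordings of this experiment are publicly deposited, so the package
generates its own: a digital twin of the heating rig plus a generative model
of the cell.

**Thermal plant.** The bath responds to laser power as a first-order system
$\tau\dot T = -(T - T_{amb}) + gP$ with $\tau = 34.2$ ms, the measured rise
time of fibre-coupled IR heating at the pipette tip (independent of power).
The static gain default $g = 60$ K per unit power gives ~12 K of headroom
above the hottest protocol setpoint (71.7 °C from 23.5 °C ambient) at full
power, mirroring a rig calibrated so its maximum diode current over-reaches
the hottest target. Integration uses the exact zero-order-hold update
$T \leftarrow T + (1-e^{-\Delta t/\tau})(T_{amb} + gP - T)$, so the
simulated step response carries the plant time constant exactly rather than
a first-order-Euler approximation of it.

**PID control.** The laser power is set by a discrete PID loop on the error
$e = T_{set} - T$ (positive error commands heating — the controller drives a
heat-only actuator), with output clamped to $[0, P_{max}]$ and the integral
state clamped so the integral term alone respects the limits (anti-windup).
Default gains cancel the plant pole ($k_i = k_p/\tau$) and place the
closed-loop time constant at 10 ms, settling well inside 100 ms with no
overshoot; the derivative gain defaults to zero, as differentiating a noisy
current-derived temperature buys nothing here. Gains live in the pipeline
configuration, not in code.

**Generative cell model.** The whole-cell current density at temperature
$T$ is

$$i(T) = i_{leak}\,a_{leak}(T) + i_{max}\,a_{i}(T)\,P_o(T), \qquad
a(T) = \exp\!\Big[\frac{\Delta H_{cond}}{R}\Big(\frac{1}{T_{ref}} -
\frac{1}{T}\Big)\Big],$$

scaled to pA by the membrane capacitance, plus Gaussian noise. The two
Arrhenius factors model the temperature dependence of the leak and of the
open-channel (unitary) conductivity. Amplitudes are anchored at
$T_{ref} = 23.5$ °C: this is algebraically identical to writing absolute
prefactors $I\,e^{-\Delta H_{cond}/RT}$ but keeps fitted amplitudes on the
pA/pF scale of the data instead of astronomically large prefactors
multiplying astronomically small exponentials.

Defaults (all configurable): leak $-2$ pA/pF and maximal channel density
$-30$ pA/pF at reference (inward at $-30$ mV holding, hence negative),
conductivity enthalpies $3.84$ kcal/mol for both components
(electrolyte-like — ionic conduction through a pore and through the seal
share the mobility physics of the bath solution), capacitance 15 pF (a
typical HEK293T cell), and measurement noise of 2 % of the maximal channel
current. These produce sweeps with end-of-pulse currents of a few hundred
pA to a few nA across the protocol, the magnitude range seen in whole-cell
heat-activation recordings.

**What the twin does not emulate.** Single-channel (shot/gating) noise and
the slow activation kinetics of the channel protein (sweeps reach their
steady state through the thermal plant only); the sinusoidal ripple of the
laser's on–off modulation; temperature gradients across the cell;
between-cell biological variability (off by default — every synthetic cell
shares the preset ground truth, so cohort SEMs measure noise-propagation
only; normal jitter on the generative parameters can be switched on).
Passing recovery tests on these data therefore demonstrates that the
analysis chain is unbiased and noise-stable for a cell obeying the model —
not that real cells obey a two-state model, which is an assumption the
experiment itself must justify.

## The analysis chain

Per cell, mirroring the experimental workflow:

1. **Steady-state extraction** — each sweep is reduced to the mean current
   over the final 50 ms of the pulse (the published procedure says only "at
   the end of the pulse"; 50 ms at 10 kHz averages 500 samples while staying
   within the settled plateau), paired with the temperature that the
   experiment's own calibration table assigns to that command level, and
   normalised by capacitance.
2. **Boltzmann fit** — the magnitude of the density-temperature relation is
   fitted with the leak + channel model above (inward currents are negated;
   polarity is restored on output). Six parameters: two amplitudes, two
   conductivity enthalpies, $\Delta H$ and $T_{0.5}$. The fit is two-stage:
   a coarse grid over $(\Delta H, T_{0.5})$ with the leak frozen at a
   low-temperature Arrhenius estimate and the amplitude solved linearly,
   then bounded Levenberg–Marquardt refinement of all six parameters from
   multiple starts, keeping the lowest sum of squares. Conductivity
   enthalpies are bounded to $[0, 15]$ kcal/mol so they cannot exchange
   with the gating enthalpy (conductivity enthalpies are small,
   electrolyte-scale; gating enthalpies of thermoTRPs are an order of
   magnitude larger). $\Delta H_i$ and $\Delta H_{leak}$ are fitted
   independently — constraining them equal would be an extra assumption the
   data can decide instead.
3. **Correction to open probability** —
   $P_o(T) = (|i|(T) - L\,a_{leak}(T))/(A\,a_i(T))$. Values outside (0, 1)
   (noise below the fitted leak, or above saturation) are flagged and
   excluded from the regression with their count reported, never silently
   dropped.
4. **van't Hoff regression** — ordinary least squares of
   $\ln(P_o/(1-P_o))$ on $1/T$; slope $-\Delta H/R$, intercept
   $\Delta S/R$. On exact two-state data the relation is perfectly linear,
   so this step is exact — a property the test suite asserts. Only points
   with $P_o \in [0.02, 0.98]$ enter (the logit amplifies noise without
   bound at the scale ends; the window is this package's choice, as
   published methods are silent on it). The regression, not the Boltzmann
   stage, supplies the reported $\Delta H$ and $\Delta S$, matching the
   published two-stage procedure.
5. **Derived parameters** — $T_{0.1}$, $T_{0.5}$, $T_{0.9}$ by analytic
   inversion, $Q_{10}$ at $T_{0.5}$ over the $[T_{0.5}, T_{0.5}+10]$
   interval (the centring convention is exposed as an argument; published
   usage is ambiguous between midpoint- and threshold-centred values), and
   $\Delta G$ over a 20–70 °C grid.
6. **Cohort aggregation** — mean ± SEM per parameter, per-cell
   $(\Delta H, \Delta S)$ pairs, and the enthalpy–entropy compensation
   regression of $\Delta H$ on $\Delta S$, whose slope (in K) approximates
   the cohort midpoint temperature — a diagnostic that the cells share one
   activation process.

A note on thresholds: the analytic $T_{0.1}$ computed from cohort-mean
$(\Delta H, \Delta S)$ is not the same number as the mean of per-cell
$T_{0.1}$ values unless the cells are identical (the map from parameters to
threshold is nonlinear); for the RpTRPA5B preset the analytic value is
~52.1 °C while published summaries quote 53 °C. The cohort summary reports
the mean of per-cell values; the analytic value from any parameter pair is a
one-liner via `temperature_at_open_probability()`.

## Numerical and reproducibility choices

* Logistics are evaluated with `plogis`, which is stable in both tails.
* The LM refinement starts from both the log-Arrhenius leak estimate and an
  electrolyte-like fallback; amplitude starts are floored at $10^{-3}$ of
  the data scale because an exactly-zero amplitude makes the Jacobian
  singular before the optimiser can move. Degenerate inputs (leak-only or
  channel-only cells) then converge cleanly with the absent component's
  amplitude at its zero bound.
* All randomness is Mersenne–Twister with inversion-method normals; every
  generator takes an explicit seed, restores the caller's RNG state, and a
  given seed reproduces a recording bit-for-bit.
* Configs are serialised to JSON with 17 significant digits, so a stored
  configuration reproduces its run file-for-file.
* Problem sizes used throughout the examples and checks: 12 setpoints
  spanning 23.5–71.7 °C, 700-ms pulses at 10 kHz with a 100-ms baseline,
  cohorts of 8 cells at 2 % noise — the conditions of the study this
  pipeline models.

## Known limitations

The two-state model ignores intermediate and adsorbed states, voltage
dependence (the −30 mV holding potential is metadata, not a model input) and
activation kinetics; it describes equilibrium occupancy only. The
thermometry model assumes the pipette and cell experience the same
temperature field. The Boltzmann fit requires both sub-threshold and
near-saturating coverage — protocols narrower than ~25 °C are rejected
rather than fitted badly. Fit uncertainties come from the Jacobian at the
optimum and inherit its local-linearity assumptions; a bootstrap across
cells is the recommended alternative when cohort sizes allow.
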