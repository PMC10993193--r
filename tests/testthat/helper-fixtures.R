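# Shared fixtures: presets built in code, reduced-rate protocols for speed.

rp_gating <- function() gating_thermodynamics(72.6, t_half_c = 58.6)

# default 12-step protocol of the study conditions
study_protocol <- function(sample_rate = 10000) {
  stimulus_protocol(seq(23.5, 71.7, length.out = 12),
                    pulse_duration = 0.7, inter_pulse = 0.1,
                    sample_rate = sample_rate)
}

# a fast low-rate protocol for unit tests that only need steady states
fast_protocol <- function(setpoints = seq(23.5, 71.7, length.out = 12)) {
  stimulus_protocol(setpoints, pulse_duration = 0.7, inter_pulse = 0.1,
                    sample_rate = 2000)
}

# analytic steady-state point set straight from the generative closed form
# (no instrument in the loop) -- used as an exact oracle for the fits
analytic_points <- function(cell, temps_k) {
  dens <- cell$i_leak_ref *
    thermogating:::arrhenius_scale(cell$dh_leak, cell$t_ref_k, temps_k) +
    cell$i_max_ref *
      thermogating:::arrhenius_scale(cell$dh_i, cell$t_ref_k, temps_k) *
      open_probability(cell$gating, temps_k)
  structure(
    data.frame(command_level = kelvin_to_celsius(temps_k),
               temperature_k = temps_k,
               current_pa = dens * cell$capacitance_pf,
               density_pa_pf = dens),
    cell_id = cell$label, capacitance_pf = cell$capacitance_pf,
    t_ref_k = cell$t_ref_k, temperature_source = "analytic",
    class = c("steady_state_points", "data.frame")
  )
}

# random heat-activated gating parameters for property-style tests
random_gating <- function(n) {
  delta_h <- stats::runif(n, 20, 150)
  t_half_c <- stats::runif(n, 30, 70)
  lapply(seq_len(n), function(i) {
    gating_thermodynamics(delta_h[i], t_half_c = t_half_c[i])
  })
}
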