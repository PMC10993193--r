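#' Sweep constructor and validator
#'
#' A sweep is the unit time series of the package: a data frame with columns
#' `time_s` (strictly increasing, seconds) and `current_pa` (pA), optionally
#' tagged with the laser `command_level` that produced it.
#'
#' @param time_s Strictly increasing time axis, seconds.
#' @param current_pa Current samples, pA; same length as `time_s`.
#' @param command_level Optional scalar identifying the stimulus level (for
#'   synthetic data the setpoint in degrees Celsius).
#' @return A data frame of class `sweep_trace`.
#' @export
new_sweep <- function(time_s, current_pa, command_level = NULL) {
  sweep <- data.frame(time_s = time_s, current_pa = current_pa)
  attr(sweep, "command_level") <- command_level
  class(sweep) <- c("sweep_trace", "data.frame")
  validate_sweep(sweep)
}

#' @rdname new_sweep
#' @param sweep Object to validate.
#' @export
validate_sweep <- function(sweep) {
  if (!is.data.frame(sweep) ||
      !all(c("time_s", "current_pa") %in% names(sweep))) {
    stop("a sweep is a data frame with columns time_s and current_pa",
         call. = FALSE)
  }
  if (nrow(sweep) < 2L || any(diff(sweep$time_s) <= 0)) {
    stop("sweep time axis must be strictly increasing with >= 2 samples",
         call. = FALSE)
  }
  if (any(!is.finite(sweep$current_pa))) {
    stop("sweep currents must be finite", call. = FALSE)
  }
  invisible(sweep)
}

#' PID controller gains
#'
#' Gains of the discrete proportional-integral-derivative loop that drives
#' the infrared laser. The error convention is `setpoint - measured`, so a
#' positive error commands heating; the output (laser power, arbitrary
#' units) is clamped to `output_limits` and the integral state is clamped so
#' that the integral term alone stays within the limits (anti-windup).
#'
#' Defaults are tuned for the default [heating_plant()]: the integral zero
#' cancels the plant pole (`ki = kp / tau`) giving a first-order closed loop
#' with a 10 ms time constant, which settles well within 100 ms without
#' overshoot.
#'
#' @param kp Proportional gain, power units per K.
#' @param ki Integral gain, power units per (K s).
#' @param kd Derivative gain, power units s per K.
#' @param output_limits Length-2 `c(0, P_max)` clamp on the commanded power.
#' @return An object of class `pid_gains`.
#' @export
pid_gains <- function(kp = 0.057, ki = kp / 0.0342, kd = 0,
                      output_limits = c(0, 1)) {
  if (any(c(kp, ki, kd) < 0)) stop("gains must be >= 0", call. = FALSE)
  if (length(output_limits) != 2L || output_limits[2] <= output_limits[1]) {
    stop("output_limits must be c(min, max) with max > min", call. = FALSE)
  }
  structure(list(kp = kp, ki = ki, kd = kd, output_limits = output_limits),
            class = "pid_gains")
}

#' First-order thermal plant of the laser heating rig
#'
#' The bath temperature at the pipette tip responds to laser power as a
#' single-pole low-pass system:
#' \deqn{\tau \dot T = -(T - T_{amb}) + g P,}
#' with time constant `tau` (default 34.2 ms, the measured rise time of the
#' rig, independent of laser power), static gain `gain` (K per power unit)
#' and ambient (room) temperature `ambient_k`.
#'
#' @param tau Thermal time constant, seconds.
#' @param gain Steady-state temperature rise per unit laser power, K.
#' @param ambient_k Ambient temperature, Kelvin (default 23.5 C).
#' @return An object of class `heating_plant`.
#' @export
heating_plant <- function(tau = 0.0342, gain = 60, ambient_k = 296.65) {
  if (tau <= 0 || gain <= 0) stop("tau and gain must be > 0", call. = FALSE)
  check_kelvin(ambient_k, "ambient_k")
  structure(list(tau = tau, gain = gain, ambient_k = ambient_k),
            class = "heating_plant")
}

#' Temperature-step stimulus protocol
#'
#' @param setpoints_c Target temperatures of the pulses, degrees Celsius.
#' @param pulse_duration Pulse length, seconds (default 0.7).
#' @param inter_pulse Pre-pulse baseline recorded at ambient before each
#'   pulse, seconds (default 0.1).
#' @param sample_rate Sampling rate, Hz (>= 1000; default 10000).
#' @return An object of class `stimulus_protocol`.
#' @examples
#' stimulus_protocol(seq(23.5, 71.7, length.out = 12))
#' @export
stimulus_protocol <- function(setpoints_c, pulse_duration = 0.7,
                              inter_pulse = 0.1, sample_rate = 10000) {
  if (length(setpoints_c) > 0 && any(!is.finite(setpoints_c))) {
    stop("setpoints must be finite", call. = FALSE)
  }
  if (pulse_duration <= 0 || inter_pulse < 0) {
    stop("durations must be positive", call. = FALSE)
  }
  if (sample_rate < 1000) stop("sample_rate must be >= 1 kHz", call. = FALSE)
  structure(list(setpoints_c = as.numeric(setpoints_c),
                 pulse_duration = pulse_duration,
                 inter_pulse = inter_pulse,
                 sample_rate = sample_rate),
            class = "stimulus_protocol")
}

#' Generative parameters of one recorded cell
#'
#' Everything needed to synthesise whole-cell current sweeps from a patched
#' cell expressing a heat-gated channel: the two-state gating
#' thermodynamics, the maximal channel current density and its conductivity
#' temperature dependence, a temperature-dependent leak, membrane
#' capacitance and measurement noise. Current densities are signed: at a
#' -30 mV holding potential both leak and channel currents are inward,
#' hence negative.
#'
#' Leak and channel conductivity follow Arrhenius laws re-parameterised
#' relative to the reference temperature `t_ref_k`:
#' \deqn{I(T) = I_{ref} \exp\left(\frac{1000\,\Delta H}{R}
#'   \left(\frac{1}{T_{ref}} - \frac{1}{T}\right)\right),}
#' which is mathematically identical to an absolute Arrhenius prefactor but
#' keeps the fitted amplitudes on the pA/pF scale of the data.
#'
#' @param gating A [gating_thermodynamics()] object.
#' @param i_max_ref Maximal (fully open) channel current density at
#'   `t_ref_k`, pA/pF; negative for inward current.
#' @param dh_i Conductivity enthalpy of the open-channel current, kcal/mol.
#' @param i_leak_ref Leak current density at `t_ref_k`, pA/pF.
#' @param dh_leak Conductivity enthalpy of the leak, kcal/mol.
#' @param capacitance_pf Membrane capacitance, pF.
#' @param holding_mv Holding potential, mV (metadata only).
#' @param noise_sd_fraction Gaussian measurement noise SD as a fraction of
#'   the maximal channel current `|i_max_ref| * capacitance_pf`.
#' @param t_ref_k Reference temperature for the Arrhenius amplitudes, K.
#' @param label Free-text cell/channel label.
#' @return An object of class `cell_parameters`.
#' @export
cell_parameters <- function(gating,
                            i_max_ref = -30, dh_i = 3.84,
                            i_leak_ref = -2, dh_leak = 3.84,
                            capacitance_pf = 15, holding_mv = -30,
                            noise_sd_fraction = 0.02,
                            t_ref_k = 296.65, label = "cell") {
  stopifnot(inherits(gating, "gating_thermodynamics"))
  if (capacitance_pf <= 0) stop("capacitance must be > 0", call. = FALSE)
  if (noise_sd_fraction < 0) stop("noise_sd_fraction must be >= 0", call. = FALSE)
  if (dh_i < 0 || dh_leak < 0) stop("dh_i and dh_leak must be >= 0", call. = FALSE)
  check_kelvin(t_ref_k, "t_ref_k")
  structure(list(gating = gating, i_max_ref = i_max_ref, dh_i = dh_i,
                 i_leak_ref = i_leak_ref, dh_leak = dh_leak,
                 capacitance_pf = capacitance_pf, holding_mv = holding_mv,
                 noise_sd_fraction = noise_sd_fraction,
                 t_ref_k = t_ref_k, label = label),
            class = "cell_parameters")
}

#' @export
print.cell_parameters <- function(x, ...) {
  cat(sprintf("Cell parameters [%s]\n", x$label))
  cat(sprintf("  gating: dH = %.4g kcal/mol, dS = %.4g cal/(mol K)\n",
              x$gating$delta_h, x$gating$delta_s))
  cat(sprintf("  i_max_ref = %.3g pA/pF (dh_i = %.3g), leak = %.3g pA/pF (dh_leak = %.3g)\n",
              x$i_max_ref, x$dh_i, x$i_leak_ref, x$dh_leak))
  cat(sprintf("  Cm = %.3g pF, %.0f mV, noise %.1f%%, T_ref = %.2f K\n",
              x$capacitance_pf, x$holding_mv, 100 * x$noise_sd_fraction,
              x$t_ref_k))
  invisible(x)
}

# Arrhenius amplitude scale relative to t_ref (shared by generator and fit)
arrhenius_scale <- function(dh_kcal, t_ref_k, temp_k) {
  exp((1000 * dh_kcal / GAS_CONSTANT_CAL) * (1 / t_ref_k - 1 / temp_k))
}

# run code with a temporarily seeded RNG, restoring the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Simulate one PID-controlled temperature pulse
#'
#' Discrete-time PID loop around the first-order thermal plant. The error is
#' `setpoint - measured`; the commanded power is clamped to the actuator
#' limits with integral clamping as anti-windup. The plant is advanced with
#' the exact zero-order-hold update
#' `T <- T + (1 - exp(-dt/tau)) * (ambient + gain * P - T)`, so the
#' open-loop step response reproduces the plant time constant exactly.
#'
#' @param plant A [heating_plant()].
#' @param gains A [pid_gains()].
#' @param setpoint_c Target temperature, degrees Celsius.
#' @param duration Pulse duration, seconds (must be >= 10 tau).
#' @param dt Controller/sampling interval, seconds (must be <= tau / 5).
#' @return Data frame with columns `time_s`, `temperature_k`, `power`.
#' @examples
#' pulse <- simulate_pid_pulse(heating_plant(), pid_gains(), 58.6)
#' mean(tail(pulse$temperature_k, 1000))  # ~331.75 K
#' @export
simulate_pid_pulse <- function(plant, gains, setpoint_c,
                               duration = 0.7, dt = 1e-4) {
  stopifnot(inherits(plant, "heating_plant"), inherits(gains, "pid_gains"))
  if (dt > plant$tau / 5) {
    stop("dt must be <= tau/5 for a faithful discrete loop", call. = FALSE)
  }
  if (duration < 10 * plant$tau) {
    stop("duration must be >= 10 tau to reach steady state", call. = FALSE)
  }
  setpoint_k <- celsius_to_kelvin(setpoint_c)
  n <- as.integer(round(duration / dt))
  time_s <- (seq_len(n) - 1L) * dt
  temp <- numeric(n)
  power <- numeric(n)
  t_now <- plant$ambient_k
  integ <- 0
  err_prev <- setpoint_k - t_now
  decay <- 1 - exp(-dt / plant$tau)
  lims <- gains$output_limits
  for (k in seq_len(n)) {
    temp[k] <- t_now
    err <- setpoint_k - t_now
    integ <- integ + err * dt
    if (gains$ki > 0) {  # anti-windup: integral term alone within limits
      integ <- min(max(integ, lims[1] / gains$ki), lims[2] / gains$ki)
    }
    out <- gains$kp * err + gains$ki * integ + gains$kd * (err - err_prev) / dt
    out <- min(max(out, lims[1]), lims[2])
    power[k] <- out
    err_prev <- err
    t_now <- t_now + decay * (plant$ambient_k + plant$gain * out - t_now)
    if (!is.finite(t_now) || abs(t_now) > 500 + plant$ambient_k) {
      stop(sprintf(
        "PID simulation unstable (|T| diverged) with kp=%g ki=%g kd=%g",
        gains$kp, gains$ki, gains$kd), call. = FALSE)
    }
  }
  data.frame(time_s = time_s, temperature_k = temp, power = power)
}

#' Open-loop step response of the thermal plant
#'
#' Applies a constant laser power (no feedback) and returns the resulting
#' temperature trace; fitting an exponential to it recovers the plant time
#' constant. Mainly a diagnostic for the digital twin.
#'
#' @inheritParams simulate_pid_pulse
#' @param power Constant laser power, same units as the PID output.
#' @return Data frame with columns `time_s`, `temperature_k`.
#' @export
simulate_open_loop_step <- function(plant, power, duration = 0.7, dt = 1e-4) {
  stopifnot(inherits(plant, "heating_plant"))
  n <- as.integer(round(duration / dt))
  time_s <- (seq_len(n) - 1L) * dt
  temp <- numeric(n)
  t_now <- plant$ambient_k
  decay <- 1 - exp(-dt / plant$tau)
  target <- plant$ambient_k + plant$gain * power
  for (k in seq_len(n)) {
    temp[k] <- t_now
    t_now <- t_now + decay * (target - t_now)
  }
  data.frame(time_s = time_s, temperature_k = temp)
}

# full-sweep temperature waveform: ambient baseline then PID-controlled pulse
protocol_waveforms <- function(protocol, plant, gains) {
  dt <- 1 / protocol$sample_rate
  n_base <- as.integer(round(protocol$inter_pulse / dt))
  lapply(protocol$setpoints_c, function(sp) {
    pulse <- simulate_pid_pulse(plant, gains, sp,
                                duration = protocol$pulse_duration, dt = dt)
    time_s <- (seq_len(n_base + nrow(pulse)) - 1L) * dt
    data.frame(
      time_s = time_s,
      temperature_k = c(rep(plant$ambient_k, n_base), pulse$temperature_k)
    )
  })
}

#' Simulate an open-pipette calibration sweep
#'
#' Converts a temperature waveform to the current that an open patch pipette
#' would report through the Arrhenius conductivity relation:
#' `current(t) = I0 * current_ratio_for_temperature(T(t))`, plus optional
#' Gaussian noise.
#'
#' @param cal A [temperature_calibration()].
#' @param waveform Data frame with columns `time_s`, `temperature_k`.
#' @param noise_sd_fraction Gaussian noise SD as a fraction of `|I0|`.
#' @param seed Optional RNG seed (noise only).
#' @param command_level Stimulus tag stored on the returned sweep.
#' @return A `sweep_trace` (see [new_sweep()]).
#' @export
simulate_open_pipette_sweep <- function(cal, waveform,
                                        noise_sd_fraction = 0, seed = NULL,
                                        command_level = NULL) {
  stopifnot(inherits(cal, "temperature_calibration"))
  current <- cal$i0 * current_ratio_for_temperature(cal, waveform$temperature_k)
  if (noise_sd_fraction > 0) {
    current <- current + with_seed(seed,
      stats::rnorm(length(current), 0, noise_sd_fraction * abs(cal$i0)))
  }
  new_sweep(waveform$time_s, current, command_level = command_level)
}

#' Synthesise one whole-cell current sweep
#'
#' Per sample, the current density (pA/pF) is
#' \deqn{i(T) = i_{leak,ref}\,a_{leak}(T) +
#'       i_{max,ref}\,a_{i}(T)\,P_o(T),}
#' where \eqn{a(T)} are the Arrhenius conductivity scales of
#' [cell_parameters()] and \eqn{P_o} the two-state open probability. The
#' density is scaled by the membrane capacitance to pA and Gaussian noise
#' with SD `noise_sd_fraction * |i_max_ref * capacitance_pf|` is added.
#'
#' @param cell A [cell_parameters()] object.
#' @param waveform Data frame with columns `time_s`, `temperature_k`.
#' @param seed Optional RNG seed; a given seed reproduces the sweep exactly.
#' @param command_level Stimulus tag stored on the returned sweep.
#' @return A `sweep_trace`.
#' @export
synthesize_sweep <- function(cell, waveform, seed = NULL,
                             command_level = NULL) {
  stopifnot(inherits(cell, "cell_parameters"))
  temp_k <- waveform$temperature_k
  check_kelvin(temp_k, "waveform temperature")
  dens <- cell$i_leak_ref * arrhenius_scale(cell$dh_leak, cell$t_ref_k, temp_k) +
    cell$i_max_ref * arrhenius_scale(cell$dh_i, cell$t_ref_k, temp_k) *
      open_probability(cell$gating, temp_k)
  current <- dens * cell$capacitance_pf
  if (cell$noise_sd_fraction > 0) {
    sd_pa <- cell$noise_sd_fraction * abs(cell$i_max_ref * cell$capacitance_pf)
    current <- current + with_seed(seed,
      stats::rnorm(length(current), 0, sd_pa))
  }
  new_sweep(waveform$time_s, current, command_level = command_level)
}

#' Synthesise a complete cell recording
#'
#' Runs the digital twin end to end for one cell: a PID-controlled
#' temperature pulse per protocol setpoint, converted to whole-cell current
#' sweeps through the generative cell model. The true temperature waveforms
#' are kept alongside the sweeps — synthetic recordings always carry their
#' ground truth.
#'
#' @param cell A [cell_parameters()].
#' @param protocol A [stimulus_protocol()].
#' @param plant A [heating_plant()].
#' @param gains A [pid_gains()].
#' @param seed RNG seed controlling the measurement noise of this cell.
#' @param cell_id Identifier stored in the metadata.
#' @param waveforms Optional pre-computed list of temperature waveforms (one
#'   per setpoint, from the same protocol/plant/gains); avoids re-running
#'   the PID simulation when many cells share a protocol.
#' @return An object of class `channel_recording`: list with elements
#'   `sweeps` (list of `sweep_trace`), `true_temperature` (list of
#'   waveforms) and `metadata`.
#' @export
synthesize_cell_recording <- function(cell, protocol,
                                      plant = heating_plant(),
                                      gains = pid_gains(),
                                      seed = 1L, cell_id = cell$label,
                                      waveforms = NULL) {
  stopifnot(inherits(cell, "cell_parameters"),
            inherits(protocol, "stimulus_protocol"))
  if (is.null(waveforms)) {
    waveforms <- protocol_waveforms(protocol, plant, gains)
  }
  sweeps <- with_seed(seed, lapply(seq_along(waveforms), function(i) {
    synthesize_sweep(cell, waveforms[[i]],
                     command_level = protocol$setpoints_c[i])
  }))
  structure(
    list(
      sweeps = sweeps,
      true_temperature = waveforms,
      metadata = list(
        cell_id = cell_id,
        label = cell$label,
        capacitance_pf = cell$capacitance_pf,
        holding_mv = cell$holding_mv,
        t_ref_k = cell$t_ref_k,
        seed = seed,
        setpoints_c = protocol$setpoints_c,
        pulse_duration = protocol$pulse_duration,
        inter_pulse = protocol$inter_pulse,
        sample_rate = protocol$sample_rate,
        synthetic = TRUE
      )
    ),
    class = "channel_recording"
  )
}

#' @export
print.channel_recording <- function(x, ...) {
  m <- x$metadata
  cat(sprintf("Channel recording [%s]: %d sweeps at %g Hz, Cm = %g pF, %g mV\n",
              m$cell_id, length(x$sweeps), m$sample_rate,
              m$capacitance_pf, m$holding_mv))
  invisible(x)
}

#' Synthesise a cohort of recordings
#'
#' Generates `length(seeds)` cells sharing one generative ground truth (the
#' preset); only the measurement noise differs between cells unless
#' between-cell `jitter` is requested. This mirrors a cohort of biological
#' replicates recorded under an identical stimulation protocol.
#'
#' @inheritParams synthesize_cell_recording
#' @param seeds Integer vector, one RNG seed per cell; duplicates trigger a
#'   warning (cells would be identical).
#' @param jitter Optional named list of between-cell SDs applied as normal
#'   perturbations to the generative parameters (`delta_h`, `t_half_c`,
#'   `i_max_ref`, `i_leak_ref`, `capacitance_pf`); default none.
#' @return List of `channel_recording` objects.
#' @export
synthesize_cohort <- function(cell, protocol,
                              plant = heating_plant(), gains = pid_gains(),
                              seeds = 1:8, jitter = NULL) {
  if (length(seeds) < 1L) stop("need at least one seed", call. = FALSE)
  if (anyDuplicated(seeds)) {
    warning("duplicate seeds: the corresponding cells will be identical")
  }
  waveforms <- protocol_waveforms(protocol, plant, gains)
  lapply(seq_along(seeds), function(j) {
    cj <- cell
    if (!is.null(jitter)) {
      cj <- with_seed(seeds[j] + 500000L, jitter_cell(cell, jitter))
    }
    synthesize_cell_recording(
      cj, protocol, plant, gains,
      seed = seeds[j],
      cell_id = sprintf("%s_cell%02d", cell$label, j),
      waveforms = waveforms
    )
  })
}

# apply normal between-cell perturbations to selected generative parameters
jitter_cell <- function(cell, jitter) {
  g <- cell$gating
  delta_h <- g$delta_h + if (!is.null(jitter$delta_h))
    stats::rnorm(1, 0, jitter$delta_h) else 0
  t_half_k <- 1000 * g$delta_h / g$delta_s +
    if (!is.null(jitter$t_half_c)) stats::rnorm(1, 0, jitter$t_half_c) else 0
  cell_parameters(
    gating = gating_thermodynamics(delta_h,
                                   t_half_c = kelvin_to_celsius(t_half_k)),
    i_max_ref = cell$i_max_ref + if (!is.null(jitter$i_max_ref))
      stats::rnorm(1, 0, jitter$i_max_ref) else 0,
    dh_i = cell$dh_i,
    i_leak_ref = cell$i_leak_ref + if (!is.null(jitter$i_leak_ref))
      stats::rnorm(1, 0, jitter$i_leak_ref) else 0,
    dh_leak = cell$dh_leak,
    capacitance_pf = max(cell$capacitance_pf + if (!is.null(jitter$capacitance_pf))
      stats::rnorm(1, 0, jitter$capacitance_pf) else 0, 1),
    holding_mv = cell$holding_mv,
    noise_sd_fraction = cell$noise_sd_fraction,
    t_ref_k = cell$t_ref_k,
    label = cell$label
  )
}

#' Simulate an open-pipette calibration recording for a protocol
#'
#' Runs the PID rig once per setpoint with no cell on the pipette and
#' returns the open-pipette sweeps, ready for [calibrate_protocol()]. This
#' is the in-silico analogue of the per-experiment calibration run.
#'
#' @inheritParams synthesize_cell_recording
#' @param cal A [temperature_calibration()] describing the pipette.
#' @param noise_sd_fraction Gaussian noise on the pipette current, as a
#'   fraction of `|I0|`.
#' @param seed Optional RNG seed for the noise.
#' @return List of `sweep_trace` objects tagged with their command levels.
#' @export
simulate_calibration_run <- function(cal, protocol,
                                     plant = heating_plant(),
                                     gains = pid_gains(),
                                     noise_sd_fraction = 0, seed = NULL,
                                     waveforms = NULL) {
  if (is.null(waveforms)) {
    waveforms <- protocol_waveforms(protocol, plant, gains)
  }
  with_seed(seed, lapply(seq_along(waveforms), function(i) {
    simulate_open_pipette_sweep(cal, waveforms[[i]],
                                noise_sd_fraction = noise_sd_fraction,
                                command_level = protocol$setpoints_c[i])
  }))
}
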