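# Digital twin of the PID-controlled heating rig and the generative
# whole-cell recording model.

test_that("setpoint at ambient gives zero power and a flat trace", {
  plant <- heating_plant()
  pulse <- simulate_pid_pulse(plant, pid_gains(), 23.5, dt = 5e-4)
  expect_true(all(pulse$power == 0))
  expect_true(all(pulse$temperature_k == plant$ambient_k))
})

test_that("default gains settle within 0.5 C of the setpoint", {
  for (sp in c(40, 58.6, 71.7)) {
    pulse <- simulate_pid_pulse(heating_plant(), pid_gains(), sp, dt = 1e-4)
    tail_mean <- mean(pulse$temperature_k[pulse$time_s >= 0.6])
    expect_lt(abs(tail_mean - celsius_to_kelvin(sp)), 0.5)
  }
})

test_that("integral action makes the steady state independent of kp", {
  ss <- vapply(c(0.02, 0.057, 0.15), function(kp) {
    g <- pid_gains(kp = kp, ki = 1.667)
    pulse <- simulate_pid_pulse(heating_plant(), g, 58.6, dt = 1e-4)
    mean(pulse$temperature_k[pulse$time_s >= 0.6])
  }, numeric(1))
  expect_lt(max(ss) - min(ss), 0.05)
})

test_that("open-loop step response recovers the plant time constant", {
  plant <- heating_plant(tau = 0.0342, gain = 60, ambient_k = 296.65)
  step <- simulate_open_loop_step(plant, power = 0.5, duration = 0.7,
                                  dt = 1e-4)
  # T(t) = T_inf - (T_inf - T0) exp(-t/tau): regress log residual on time
  t_inf <- step$temperature_k[nrow(step)]
  expect_equal(t_inf, 296.65 + 30, tolerance = 1e-6)
  early <- step[step$time_s <= 0.15, ]
  reg <- stats::lm(log(t_inf - temperature_k) ~ time_s, data = early)
  tau_fit <- -1 / unname(stats::coef(reg)["time_s"])
  expect_equal(tau_fit, 0.0342, tolerance = 0.02)
})

test_that("PID preconditions are enforced", {
  plant <- heating_plant()
  expect_error(simulate_pid_pulse(plant, pid_gains(), 50, dt = 0.05),
               "tau/5")
  expect_error(simulate_pid_pulse(plant, pid_gains(), 50, duration = 0.1),
               "10 tau")
  expect_error(pid_gains(kp = -1), ">= 0")
})

test_that("open-pipette sweeps reflect the temperature waveform", {
  cal <- temperature_calibration(t0_k = 296.65, i0 = -1000)
  # constant baseline waveform -> constant baseline current
  flat <- data.frame(time_s = seq(0, 0.1, 1e-3),
                     temperature_k = rep(296.65, 101))
  sweep <- simulate_open_pipette_sweep(cal, flat)
  expect_true(all(sweep$current_pa == -1000))
  # 700-ms PID step to 71.7 C ends near the closed-form current ratio
  protocol <- fast_protocol(71.7)
  wf <- thermogating:::protocol_waveforms(protocol, heating_plant(),
                                          pid_gains())[[1]]
  sweep <- simulate_open_pipette_sweep(cal, wf)
  end_ratio <- mean(utils::tail(sweep$current_pa, 50)) / -1000
  expect_equal(end_ratio, 2.486, tolerance = 0.01)
  # a monotone temperature ramp gives a monotone current magnitude
  ramp <- data.frame(time_s = seq(0, 0.1, 1e-3),
                     temperature_k = seq(296.65, 340, length.out = 101))
  sweep <- simulate_open_pipette_sweep(cal, ramp)
  expect_true(all(diff(abs(sweep$current_pa)) > 0))
})

test_that("synthesized currents match an independent model evaluation", {
  cell <- channel_preset("RpTRPA5B", noise_sd_fraction = 0)
  wf <- data.frame(time_s = seq(0, 0.05, 1e-3),
                   temperature_k = seq(300, 340, length.out = 51))
  sweep <- synthesize_sweep(cell, wf)
  # independent sample-by-sample evaluation in the absolute-prefactor form:
  # I(T) = [A_leak e^(-1000 dH_leak/(R T)) + A_max e^(-1000 dH_i/(R T)) Po] Cm
  R <- 1.987
  a_leak <- -2 * exp(1000 * 3.84 / (R * 296.65))
  a_max <- -30 * exp(1000 * 3.84 / (R * 296.65))
  keq <- exp(-1000 * 72.6 / (R * wf$temperature_k) +
               (1000 * 72.6 / 331.75) / R)
  expected <- (a_leak * exp(-1000 * 3.84 / (R * wf$temperature_k)) +
                 a_max * exp(-1000 * 3.84 / (R * wf$temperature_k)) *
                   keq / (1 + keq)) * 15
  expect_equal(sweep$current_pa, expected, tolerance = 1e-12)
})

test_that("leak-only cells give a pure monotone leak trace", {
  cell <- channel_preset("RpTRPA5B", i_max_ref = 0, noise_sd_fraction = 0)
  wf <- data.frame(time_s = seq(0, 0.05, 1e-3),
                   temperature_k = seq(297, 345, length.out = 51))
  sweep <- synthesize_sweep(cell, wf)
  expect_true(all(diff(abs(sweep$current_pa)) > 0))
  expect_equal(sweep$current_pa[1],
               -2 * 15 * thermogating:::arrhenius_scale(3.84, 296.65, 297),
               tolerance = 1e-12)
})

test_that("at the midpoint the channel term is half the scaled maximum", {
  cell <- channel_preset("RpTRPA5B", noise_sd_fraction = 0)
  t_half <- 331.75
  wf <- data.frame(time_s = c(0, 1e-3), temperature_k = rep(t_half, 2))
  sweep <- synthesize_sweep(cell, wf)
  leak <- -2 * thermogating:::arrhenius_scale(3.84, 296.65, t_half)
  chan <- -30 * thermogating:::arrhenius_scale(3.84, 296.65, t_half) * 0.5
  expect_equal(sweep$current_pa, rep((leak + chan) * 15, 2),
               tolerance = 1e-9)
})

test_that("sweep synthesis is reproducible under a seed", {
  cell <- channel_preset("RpTRPA5B")
  wf <- data.frame(time_s = seq(0, 0.02, 1e-3),
                   temperature_k = seq(300, 330, length.out = 21))
  s1 <- synthesize_sweep(cell, wf, seed = 42)
  s2 <- synthesize_sweep(cell, wf, seed = 42)
  s3 <- synthesize_sweep(cell, wf, seed = 43)
  expect_identical(s1$current_pa, s2$current_pa)
  expect_false(identical(s1$current_pa, s3$current_pa))
})

test_that("seeded synthesis restores the caller's RNG stream", {
  cell <- channel_preset("RpTRPA5B")
  wf <- data.frame(time_s = c(0, 1e-3), temperature_k = c(300, 300))
  set.seed(99)
  before <- stats::runif(1)
  set.seed(99)
  invisible(synthesize_sweep(cell, wf, seed = 5))
  after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("cell recordings have the promised shape and determinism", {
  cell <- channel_preset("RpTRPA5B")
  protocol <- fast_protocol()
  rec <- synthesize_cell_recording(cell, protocol, seed = 1)
  expect_s3_class(rec, "channel_recording")
  expect_length(rec$sweeps, 12)
  expect_length(rec$true_temperature, 12)
  expect_equal(nrow(rec$sweeps[[1]]), 0.8 * 2000)
  expect_equal(rec$metadata$setpoints_c, protocol$setpoints_c)
  rec2 <- synthesize_cell_recording(cell, protocol, seed = 1)
  expect_identical(rec$sweeps, rec2$sweeps)
  # empty protocol -> empty recording with valid metadata
  empty <- synthesize_cell_recording(cell, stimulus_protocol(numeric(0)),
                                     seed = 1)
  expect_length(empty$sweeps, 0)
  expect_equal(empty$metadata$capacitance_pf, 15)
})

test_that("cohorts share ground truth and warn on duplicate seeds", {
  cell <- channel_preset("RpTRPA5B", noise_sd_fraction = 0)
  protocol <- fast_protocol(c(40, 60))
  cohort <- synthesize_cohort(cell, protocol, seeds = 1:3)
  expect_length(cohort, 3)
  # zero jitter and zero noise: all cells bit-identical
  expect_identical(cohort[[1]]$sweeps[[1]]$current_pa,
                   cohort[[3]]$sweeps[[1]]$current_pa)
  expect_warning(synthesize_cohort(cell, protocol, seeds = c(1, 1)),
                 "duplicate")
  single <- synthesize_cohort(cell, protocol, seeds = 7)
  expect_length(single, 1)
})
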