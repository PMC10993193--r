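# Steady-state extraction, Boltzmann fitting, leak/conductivity correction,
# van't Hoff regression, derived parameters and cohort aggregation.

study_temps_k <- celsius_to_kelvin(seq(23.5, 71.7, length.out = 12))

test_that("steady-state extraction reproduces generator ground truth", {
  cell <- channel_preset("RpTRPA5B", noise_sd_fraction = 0)
  protocol <- fast_protocol()
  rec <- synthesize_cell_recording(cell, protocol, seed = 1)
  pts <- extract_steady_state(rec, window = 0.05,
                              temperature_source = "ground_truth")
  expect_equal(nrow(pts), 12)
  # temperatures within 0.3 C of the PID setpoints
  expect_lt(max(abs(kelvin_to_celsius(pts$temperature_k) -
                      protocol$setpoints_c)), 0.3)
  # currents within 0.5% of the closed form at the extracted temperature
  oracle <- analytic_points(cell, pts$temperature_k)
  expect_equal(pts$current_pa, oracle$current_pa, tolerance = 5e-3)
  # densities are currents over capacitance
  expect_equal(pts$density_pa_pf, pts$current_pa / 15)
})

test_that("extraction validates its window and calibration coverage", {
  cell <- channel_preset("RpTRPA5B")
  rec <- synthesize_cell_recording(cell, fast_protocol(c(40, 60)), seed = 1)
  expect_error(extract_steady_state(rec, window = 5,
                                    temperature_source = "ground_truth"),
               "window")
  # calibration table missing one command level
  cal <- temperature_calibration(t0_k = 296.65, i0 = -1000)
  sweeps <- simulate_calibration_run(cal, fast_protocol(40))
  tab <- calibrate_protocol(sweeps, steady_window = c(0.7495, 0.7995))
  expect_error(extract_steady_state(rec, tab), "command level")
  expect_error(extract_steady_state(rec), "calibration_table")
})

test_that("noiseless analytic data are recovered to below 0.1% error", {
  cell <- channel_preset("RpTRPA5B", noise_sd_fraction = 0)
  pts <- analytic_points(cell, study_temps_k)
  fit <- fit_boltzmann_model(pts)
  expect_true(fit$converged)
  expect_equal(fit$gating$delta_h, 72.6, tolerance = 1e-3)
  expect_equal(fit$gating$delta_s, 218.8395, tolerance = 1e-3)
  expect_equal(fit$i_max_ref, -30, tolerance = 1e-3)
  expect_equal(fit$i_leak_ref, -2, tolerance = 1e-3)
  expect_equal(fit$dh_i, 3.84, tolerance = 1e-3)
  expect_equal(fit$dh_leak, 3.84, tolerance = 1e-3)
  expect_true(all(is.finite(fit$std_errors)))
})

test_that("the refined optimum agrees with a brute-force grid search", {
  cell <- channel_preset("RpTRPA5B", noise_sd_fraction = 0)
  pts <- analytic_points(cell, study_temps_k)
  fit <- fit_boltzmann_model(pts)
  # independent coarse grid over (dH, T0.5) with the true nuisance
  # parameters held fixed; the SSE landscape's argmin should bracket the
  # refined optimum within one grid step
  y <- abs(pts$density_pa_pf)
  leak <- 2 * thermogating:::arrhenius_scale(3.84, 296.65, pts$temperature_k)
  amp <- 30 * thermogating:::arrhenius_scale(3.84, 296.65, pts$temperature_k)
  dh_grid <- seq(20, 150, by = 1)
  th_grid <- celsius_to_kelvin(seq(30, 70, by = 0.25))
  sse <- outer(dh_grid, th_grid, Vectorize(function(dh, th) {
    po <- thermogating:::po_two_state(pts$temperature_k, dh, th)
    sum((y - leak - amp * po)^2)
  }))
  best <- which(sse == min(sse), arr.ind = TRUE)[1, ]
  expect_lt(abs(dh_grid[best[1]] - fit$gating$delta_h), 1)
  expect_lt(abs(th_grid[best[2]] -
                  1000 * fit$gating$delta_h / fit$gating$delta_s), 0.25)
})

test_that("degenerate channel-free and leak-free data are handled", {
  # leak-only cell: channel amplitude collapses to ~0, leak recovered
  leak_only <- channel_preset("RpTRPA5B", i_max_ref = 0,
                              noise_sd_fraction = 0)
  pts <- analytic_points(leak_only, study_temps_k)
  fit <- suppressWarnings(fit_boltzmann_model(pts))
  expect_lt(abs(fit$i_max_ref), 0.05)
  expect_equal(abs(fit$i_leak_ref), 2, tolerance = 1e-2)
  expect_equal(fit$dh_leak, 3.84, tolerance = 1e-2)
  # leak correction idempotence: channel-only data refit with ~zero leak
  no_leak <- channel_preset("RpTRPA5B", i_leak_ref = 0,
                            noise_sd_fraction = 0)
  pts2 <- analytic_points(no_leak, study_temps_k)
  fit2 <- suppressWarnings(fit_boltzmann_model(pts2))
  expect_lt(abs(fit2$i_leak_ref), 0.05)
  expect_equal(fit2$gating$delta_h, 72.6, tolerance = 1e-2)
})

test_that("fit preconditions reject thin or narrow point sets", {
  cell <- channel_preset("RpTRPA5B", noise_sd_fraction = 0)
  few <- analytic_points(cell, study_temps_k[1:5])
  expect_error(fit_boltzmann_model(few), ">= 6")
  narrow <- analytic_points(cell, celsius_to_kelvin(seq(50, 70, length.out = 8)))
  expect_error(fit_boltzmann_model(narrow), "span")
})

test_that("corrected open probabilities sit on the two-state curve", {
  cell <- channel_preset("RpTRPA5B", noise_sd_fraction = 0)
  temps <- c(study_temps_k, 331.75, 341.75)  # midpoint and 68.6 C exactly
  pts <- analytic_points(cell, temps)
  fit <- fit_boltzmann_model(pts)
  po <- open_probability_series(pts, fit)
  expect_equal(nrow(po), length(temps))
  at_mid <- which(abs(po$temperature_k - 331.75) < 1e-9)
  expect_equal(po$po[at_mid], 0.5, tolerance = 1e-6)
  usable <- !po$flagged
  expect_equal(po$po[usable],
               open_probability(cell$gating, po$temperature_k[usable]),
               tolerance = 1e-6)
  # Keq ~ 25.1 near the top of the stimulation range
  k68 <- equilibrium_constant(cell$gating, celsius_to_kelvin(68.6))
  expect_equal(po$po[abs(po$temperature_k - 341.75) < 0.5],
               k68 / (1 + k68), tolerance = 0.01)
})

test_that("points under the fitted leak are flagged, not dropped", {
  cell <- channel_preset("RpTRPA5B", noise_sd_fraction = 0)
  pts <- analytic_points(cell, study_temps_k)
  # push one cold point's density above the leak magnitude (inward current
  # weaker than leak): corrected Po would be negative
  pts$density_pa_pf[1] <- pts$density_pa_pf[1] * 0.4
  fit <- fit_boltzmann_model(analytic_points(cell, study_temps_k))
  po <- open_probability_series(pts, fit)
  expect_true(po$flagged[1])
  expect_true(is.na(po$po[1]))
  vh <- vant_hoff_regression(po)
  expect_gte(vh$n_excluded, 1)
})

test_that("van't Hoff regression is exact on analytic open probabilities", {
  for (g in list(rp_gating(), gating_thermodynamics(88.3, t_half_c = 51.6),
                 gating_thermodynamics(40, t_half_c = 45))) {
    temps <- temperature_at_open_probability(g, seq(0.05, 0.95, 0.1))
    po <- structure(
      data.frame(temperature_k = temps,
                 po = open_probability(g, temps),
                 flagged = FALSE),
      class = c("po_series", "data.frame")
    )
    vh <- vant_hoff_regression(po)
    expect_equal(vh$delta_h, g$delta_h, tolerance = 1e-10)
    expect_equal(vh$delta_s, g$delta_s, tolerance = 1e-10)
    expect_equal(vh$r_squared, 1, tolerance = 1e-12)
  }
})

test_that("van't Hoff regression needs enough in-window points", {
  g <- rp_gating()
  temps <- temperature_at_open_probability(g, c(0.001, 0.005, 0.995))
  po <- structure(
    data.frame(temperature_k = temps, po = open_probability(g, temps),
               flagged = FALSE),
    class = c("po_series", "data.frame")
  )
  expect_error(vant_hoff_regression(po), "fewer than 3")
  expect_error(vant_hoff_regression(po, po_window = c(0.5, 0.4)), "po_window")
})

test_that("derived activation parameters match the printed channel values", {
  # (dH, T0.5) pairs as published for the three channels; dS derived
  rp <- derive_activation_parameters(rp_gating())
  expect_equal(rp$t_half_c, 58.6, tolerance = 1e-9)
  expect_equal(rp$q10, 25.09568, tolerance = 1e-5)
  expect_equal(rp$t_010_c, 52.111, tolerance = 1e-3)
  expect_equal(rp$t_090_c, 65.353, tolerance = 1e-3)
  v1 <- derive_activation_parameters(gating_thermodynamics(88.3,
                                                           t_half_c = 51.6))
  expect_equal(v1$t_half_c, 51.6, tolerance = 1e-9)
  a1 <- derive_activation_parameters(gating_thermodynamics(68.7,
                                                           t_half_c = 53.5))
  expect_equal(a1$t_half_c, 53.5, tolerance = 1e-9)
  # ordering invariant and free-energy zero crossing
  expect_true(rp$t_010_c < rp$t_half_c && rp$t_half_c < rp$t_090_c)
  expect_equal(
    rp$delta_g$delta_g_kcal[rp$delta_g$temp_c == 59] < 0, TRUE)
  expect_error(
    derive_activation_parameters(gating_thermodynamics(-10, delta_s = 30)),
    "heat-activated")
})

test_that("recovery error shrinks with noise and protocol density", {
  cell_err <- function(noise, n_steps) {
    cell <- channel_preset("RpTRPA5B", noise_sd_fraction = noise)
    protocol <- fast_protocol(seq(23.5, 71.7, length.out = n_steps))
    rec <- synthesize_cell_recording(cell, protocol, seed = 4)
    out <- analyze_recording(rec, temperature_source = "ground_truth")
    abs(out$vant_hoff$delta_h - 72.6) / 72.6
  }
  for (n_steps in c(12, 24)) {
    errs <- vapply(c(0.05, 0.01, 0), cell_err, numeric(1), n_steps = n_steps)
    expect_lt(errs[2], errs[1])
    expect_lt(errs[3], 1e-3)
  }
})

test_that("cohort aggregation reports means, SEMs and compensation", {
  s <- derive_activation_parameters(rp_gating())
  same <- aggregate_cohort(list(s, s, s))
  expect_equal(unname(same$sem), rep(0, 6))
  expect_equal(unname(same$mean["t_half_c"]), 58.6, tolerance = 1e-9)
  expect_message(single <- aggregate_cohort(list(s)), "single cell")
  expect_equal(unname(single$sem["delta_h"]), 0)
  # enthalpy-entropy compensation: cells sharing T0.5 = 331.75 K lie on a
  # line through the origin with slope exactly T0.5
  cells <- lapply(c(60, 72.6, 85), function(dh) {
    derive_activation_parameters(gating_thermodynamics(dh, t_half_c = 58.6))
  })
  coh <- aggregate_cohort(cells)
  expect_equal(coh$compensation_slope_k, 331.75, tolerance = 1e-6)
})
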