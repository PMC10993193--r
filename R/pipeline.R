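#' Pipeline configuration
#'
#' A fully serialisable description of one in-silico experiment: which
#' channel to emulate, the stimulus protocol, the heating rig, the pipette
#' calibration constants, the noise level, the per-cell seeds, and the fit
#' settings. Unknown keys are rejected so a typo cannot silently change an
#' analysis.
#'
#' @param preset Channel preset name (see [channel_preset()]).
#' @param setpoints_c Stimulus setpoints, Celsius.
#' @param n_steps Used when `setpoints_c` is `NULL`: number of evenly spaced
#'   setpoints between `t_min_c` and `t_max_c`.
#' @param t_min_c,t_max_c Protocol temperature range, Celsius.
#' @param pulse_duration,inter_pulse,sample_rate See [stimulus_protocol()].
#' @param plant Named list overriding [heating_plant()] defaults.
#' @param gains Named list overriding [pid_gains()] defaults.
#' @param calibration Named list overriding [temperature_calibration()]
#'   defaults (`t0_k`, `i0`, `ea_kcal`).
#' @param noise_sd_fraction Measurement noise of the synthetic cells.
#' @param seeds Integer vector of per-cell RNG seeds.
#' @param steady_window Steady-state averaging window, seconds.
#' @param po_window Open-probability inclusion window for the van't Hoff
#'   regression.
#' @param out_dir Optional output directory for artifacts.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = "RpTRPA5B",
                            setpoints_c = NULL,
                            n_steps = 12, t_min_c = 23.5, t_max_c = 71.7,
                            pulse_duration = 0.7, inter_pulse = 0.1,
                            sample_rate = 10000,
                            plant = list(), gains = list(),
                            calibration = list(),
                            noise_sd_fraction = 0.02,
                            seeds = 1:8,
                            steady_window = 0.05,
                            po_window = c(0.02, 0.98),
                            out_dir = NULL) {
  if (is.null(setpoints_c)) {
    setpoints_c <- seq(t_min_c, t_max_c, length.out = n_steps)
  }
  check_keys <- function(x, allowed, what) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop("unknown ", what, " key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  check_keys(plant, c("tau", "gain", "ambient_k"), "plant")
  check_keys(gains, c("kp", "ki", "kd", "output_limits"), "gains")
  check_keys(calibration, c("t0_k", "i0", "ea_kcal"), "calibration")
  structure(
    list(preset = preset, setpoints_c = setpoints_c,
         pulse_duration = pulse_duration, inter_pulse = inter_pulse,
         sample_rate = sample_rate, plant = plant, gains = gains,
         calibration = calibration,
         noise_sd_fraction = noise_sd_fraction, seeds = seeds,
         steady_window = steady_window, po_window = po_window,
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  # digits = I(17): doubles survive the JSON round trip bit-exactly, so a
  # stored config reproduces its run file-for-file
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = I(17), null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(pipeline_config))
  allowed <- setdiff(allowed, c("n_steps", "t_min_c", "t_max_c"))
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) {
    stop("unknown config key(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  raw$plant <- as.list(raw$plant)
  raw$gains <- as.list(raw$gains)
  raw$calibration <- as.list(raw$calibration)
  do.call(pipeline_config, raw)
}

# materialise config components
config_objects <- function(config) {
  protocol <- stimulus_protocol(config$setpoints_c,
                                pulse_duration = config$pulse_duration,
                                inter_pulse = config$inter_pulse,
                                sample_rate = config$sample_rate)
  plant <- do.call(heating_plant, config$plant)
  gains <- do.call(pid_gains, config$gains)
  cal_args <- config$calibration
  if (is.null(cal_args$i0)) cal_args$i0 <- -1000
  cal <- do.call(temperature_calibration, cal_args)
  cell <- channel_preset(config$preset,
                         noise_sd_fraction = config$noise_sd_fraction)
  list(protocol = protocol, plant = plant, gains = gains, cal = cal,
       cell = cell)
}

#' Analyse one recording end to end
#'
#' Steady-state extraction, Boltzmann fit, leak/conductivity correction to
#' open probability, van't Hoff regression and derived activation
#' parameters, for a single cell.
#'
#' @param rec A `channel_recording`.
#' @param cal_table `calibration_table` for the recording session.
#' @param window Steady-state averaging window, seconds.
#' @param po_window Open-probability window for the regression.
#' @param temperature_source See [extract_steady_state()].
#' @return List with elements `points`, `fit`, `po`, `vant_hoff`, `summary`.
#' @export
analyze_recording <- function(rec, cal_table = NULL, window = 0.05,
                              po_window = c(0.02, 0.98),
                              temperature_source = "calibration") {
  points <- extract_steady_state(rec, cal_table, window = window,
                                 temperature_source = temperature_source)
  fit <- fit_boltzmann_model(points)
  po <- open_probability_series(points, fit)
  vh <- vant_hoff_regression(po, po_window = po_window)
  list(points = points, fit = fit, po = po, vant_hoff = vh,
       summary = derive_activation_parameters(vh))
}

#' Run the full in-silico experiment and analysis
#'
#' Executes, deterministically under the config's seeds: PID temperature
#' waveform simulation (once per setpoint), a noiseless open-pipette
#' calibration run reduced to a calibration table, synthesis of one
#' recording per seed, per-cell analysis ([analyze_recording()]) and cohort
#' aggregation. When `config$out_dir` is set, writes the config, the
#' calibration table, per-cell summaries and van't Hoff point tables, the
#' cohort table and a plain-text log (seeds and versions) beside the
#' results, so that the output directory reproduces itself.
#'
#' @param config A [pipeline_config()].
#' @return List with elements `cohort` (a `cohort_summary`), `cells`
#'   (per-cell analysis lists) and `calibration` (the calibration table).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  obj <- config_objects(config)
  stage <- "simulate"
  result <- tryCatch({
    waveforms <- protocol_waveforms(obj$protocol, obj$plant, obj$gains)

    stage <- "calibrate"
    cal_sweeps <- simulate_calibration_run(obj$cal, obj$protocol,
                                           obj$plant, obj$gains,
                                           waveforms = waveforms)
    sweep_end <- obj$protocol$inter_pulse + obj$protocol$pulse_duration -
      1 / obj$protocol$sample_rate
    cal_table <- calibrate_protocol(
      cal_sweeps,
      baseline_window = c(0, 0.9 * obj$protocol$inter_pulse),
      steady_window = c(sweep_end - config$steady_window, sweep_end),
      t0_k = obj$cal$t0_k, ea_kcal = obj$cal$ea_kcal
    )

    cells <- lapply(seq_along(config$seeds), function(j) {
      stage <<- sprintf("fit cell %d (seed %d)", j, config$seeds[j])
      rec <- synthesize_cell_recording(
        obj$cell, obj$protocol, obj$plant, obj$gains,
        seed = config$seeds[j],
        cell_id = sprintf("%s_cell%02d", config$preset, j),
        waveforms = waveforms
      )
      analyze_recording(rec, cal_table, window = config$steady_window,
                        po_window = config$po_window)
    })

    stage <- "aggregate"
    cohort <- aggregate_cohort(lapply(cells, `[[`, "summary"))
    list(cohort = cohort, cells = cells, calibration = cal_table)
  }, error = function(e) {
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })

  if (!is.null(config$out_dir)) {
    write_pipeline_artifacts(config, result)
  }
  result
}

# persist everything needed to reproduce a run (no timestamps: outputs of
# identical configs are byte-identical)
write_pipeline_artifacts <- function(config, result) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  write_pipeline_config(config, out("config.json"))
  write_calibration_table(result$calibration, out("calibration_table.tsv"))
  for (j in seq_along(result$cells)) {
    cell <- result$cells[[j]]
    s <- cell$summary
    jsonlite::write_json(
      list(cell = j, seed = config$seeds[j],
           delta_h = s$delta_h, delta_s = s$delta_s,
           t_half_c = s$t_half_c, t_010_c = s$t_010_c,
           t_090_c = s$t_090_c, q10 = s$q10, r_squared = s$r_squared,
           boltzmann_converged = cell$fit$converged),
      out(sprintf("cell%02d_summary.json", j)),
      auto_unbox = TRUE, digits = NA
    )
    utils::write.table(cell$vant_hoff$points,
                       out(sprintf("cell%02d_vant_hoff.tsv", j)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.table(result$cohort$cells, out("cohort_cells.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(n = result$cohort$n,
         mean = as.list(result$cohort$mean),
         sem = as.list(result$cohort$sem),
         compensation_slope_k = result$cohort$compensation_slope_k),
    out("cohort_summary.json"), auto_unbox = TRUE, digits = NA
  )
  writeLines(c(
    sprintf("thermogating %s, R %s.%s",
            as.character(utils::packageVersion("thermogating")),
            R.version$major, R.version$minor),
    sprintf("preset: %s", config$preset),
    sprintf("seeds: %s", paste(config$seeds, collapse = " "))
  ), out("run_log.txt"))
  invisible(config$out_dir)
}
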