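#' Pipette-current thermometry calibration constants
#'
#' The ionic current through an open patch pipette rises with temperature
#' because electrolyte mobility follows an Arrhenius law. With a baseline
#' current `i0` recorded at room temperature `t0_k`, the bath temperature
#' during a heat pulse is recovered from the instantaneous current `I` as
#' \deqn{T = \left[\frac{1}{T_0} - \frac{R}{E_a}\ln\frac{I}{I_0}\right]^{-1},}
#' where `Ea` is the effective activation energy of the pipette/solution
#' system (3.84 kcal/mol for the CsCl-based internal and NaCl external
#' solutions used on the rig this package models).
#'
#' @param t0_k Baseline absolute temperature (room temperature), Kelvin.
#' @param i0 Baseline open-pipette current at `t0_k`, pA. Sign is arbitrary
#'   (set by the holding potential) but must be non-zero and shared by all
#'   currents converted with this calibration.
#' @param ea_kcal Activation energy of the pipette system, kcal/mol.
#' @return An object of class `temperature_calibration`.
#' @examples
#' cal <- temperature_calibration(t0_k = 296.65, i0 = -1000)
#' temperature_from_current(cal, -2486)
#' @export
temperature_calibration <- function(t0_k = 296.65, i0, ea_kcal = 3.84) {
  check_kelvin(t0_k, "t0_k")
  if (!is.numeric(i0) || length(i0) != 1L || !is.finite(i0) || i0 == 0) {
    stop("i0 must be a single non-zero current (pA)", call. = FALSE)
  }
  if (!is.numeric(ea_kcal) || length(ea_kcal) != 1L || ea_kcal <= 0) {
    stop("ea_kcal must be a single positive energy (kcal/mol)", call. = FALSE)
  }
  structure(
    list(t0_k = t0_k, i0 = i0, ea_kcal = ea_kcal),
    class = "temperature_calibration"
  )
}

#' @export
print.temperature_calibration <- function(x, ...) {
  cat("Pipette-current temperature calibration\n")
  cat(sprintf("  T0 = %.2f K (%.1f C), I0 = %.4g pA, Ea = %.3g kcal/mol\n",
              x$t0_k, kelvin_to_celsius(x$t0_k), x$i0, x$ea_kcal))
  invisible(x)
}

#' Convert an open-pipette current to a bath temperature
#'
#' @param cal A [temperature_calibration()] object.
#' @param current_pa Open-pipette current(s), pA; must share the sign of the
#'   calibration baseline `i0`.
#' @return Absolute temperature(s), Kelvin.
#' @export
temperature_from_current <- function(cal, current_pa) {
  stopifnot(inherits(cal, "temperature_calibration"))
  ratio <- current_pa / cal$i0
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("current must be finite, non-zero and of the same sign as i0",
         call. = FALSE)
  }
  ea_cal <- 1000 * cal$ea_kcal
  inv_t <- 1 / cal$t0_k - (GAS_CONSTANT_CAL / ea_cal) * log(ratio)
  if (any(inv_t <= 0)) {
    stop("current ratio outside the validity range of the Arrhenius ",
         "calibration (implied temperature not finite/positive)",
         call. = FALSE)
  }
  1 / inv_t
}

#' Current ratio needed to indicate a given temperature
#'
#' Exact inverse of [temperature_from_current()]:
#' \eqn{\ln(I/I_0) = (E_a/R)(1/T_0 - 1/T)}. Used to program calibration
#' waveforms that are played back to the laser diode.
#'
#' @inheritParams temperature_from_current
#' @param temp_k Target absolute temperature(s), Kelvin.
#' @return Dimensionless current ratio(s) I/I0.
#' @export
current_ratio_for_temperature <- function(cal, temp_k) {
  stopifnot(inherits(cal, "temperature_calibration"))
  check_kelvin(temp_k)
  ea_cal <- 1000 * cal$ea_kcal
  exp((ea_cal / GAS_CONSTANT_CAL) * (1 / cal$t0_k - 1 / temp_k))
}

#' Build a calibration table from open-pipette sweeps
#'
#' Each recording session calibrates its own pipette: a series of
#' open-pipette sweeps at increasing laser command levels is reduced to a
#' table of (command level, steady-state temperature, steady-state current
#' ratio). The baseline current `I0` is the mean over `baseline_window` of
#' the *first* sweep; per sweep, the steady-state current is the mean over
#' `steady_window`, converted to temperature through the Arrhenius relation.
#'
#' @param sweeps List of sweep data frames (columns `time_s`, `current_pa`),
#'   each carrying a `command_level` attribute (see [new_sweep()]).
#' @param baseline_window Numeric length-2, `c(start, end)` seconds, lying
#'   inside every sweep, over which the room-temperature baseline is read.
#' @param steady_window Numeric length-2, seconds, over which the
#'   steady-state pulse current is read; `NULL` (default) uses the final
#'   50 ms of each sweep.
#' @param t0_k Room temperature, Kelvin.
#' @param ea_kcal Pipette-system activation energy, kcal/mol.
#' @return A `calibration_table`: data frame with columns `command_level`,
#'   `temperature_k`, `current_ratio`, sorted by command level, with the
#'   underlying [temperature_calibration()] stored as attribute
#'   `"calibration"`.
#' @export
calibrate_protocol <- function(sweeps,
                               baseline_window = c(0, 0.09),
                               steady_window = NULL,
                               t0_k = 296.65,
                               ea_kcal = 3.84) {
  if (!is.list(sweeps) || length(sweeps) == 0L) {
    stop("sweeps must be a non-empty list of sweep data frames", call. = FALSE)
  }
  lapply(sweeps, validate_sweep)
  check_window <- function(win, sweep, what) {
    if (length(win) != 2L || win[1] >= win[2] ||
        win[1] < min(sweep$time_s) || win[2] > max(sweep$time_s) + 1e-9) {
      stop(what, " [", win[1], ", ", win[2], "] s lies outside the sweep",
           call. = FALSE)
    }
  }
  first <- sweeps[[1L]]
  check_window(baseline_window, first, "baseline_window")
  in_win <- function(sweep, win) {
    sel <- sweep$time_s >= win[1] & sweep$time_s <= win[2]
    mean(sweep$current_pa[sel])
  }
  i0 <- in_win(first, baseline_window)
  if (!is.finite(i0) || i0 == 0) {
    stop("baseline current is zero or undefined; cannot calibrate",
         call. = FALSE)
  }
  cal <- temperature_calibration(t0_k = t0_k, i0 = i0, ea_kcal = ea_kcal)
  rows <- lapply(sweeps, function(sweep) {
    win <- if (is.null(steady_window)) {
      c(max(sweep$time_s) - 0.05, max(sweep$time_s))
    } else {
      steady_window
    }
    check_window(win, sweep, "steady_window")
    level <- attr(sweep, "command_level")
    if (is.null(level)) {
      stop("every sweep needs a 'command_level' attribute", call. = FALSE)
    }
    i_ss <- in_win(sweep, win)
    data.frame(
      command_level = level,
      temperature_k = temperature_from_current(cal, i_ss),
      current_ratio = i_ss / i0
    )
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$command_level), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab,
            calibration = cal,
            class = c("calibration_table", "data.frame"))
}

#' Write / read a calibration table
#'
#' The table itself goes to a tab-delimited text file with a header; the
#' calibration constants (T0, I0, Ea) go to a JSON sidecar named
#' `<path>.json`.
#'
#' @param tab A `calibration_table` from [calibrate_protocol()].
#' @param path Path of the delimited table file.
#' @return `write_calibration_table()` returns `path` invisibly;
#'   `read_calibration_table()` returns the reassembled `calibration_table`.
#' @export
write_calibration_table <- function(tab, path) {
  stopifnot(inherits(tab, "calibration_table"))
  utils::write.table(as.data.frame(tab), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cal <- attr(tab, "calibration")
  jsonlite::write_json(
    list(t0_k = cal$t0_k, i0 = cal$i0, ea_kcal = cal$ea_kcal),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_calibration_table
#' @export
read_calibration_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("command_level", "temperature_k", "current_ratio")
  if (!all(need %in% names(tab))) {
    stop("calibration table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cal <- temperature_calibration(meta$t0_k, meta$i0, meta$ea_kcal)
  structure(tab[need],
            calibration = cal,
            class = c("calibration_table", "data.frame"))
}
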