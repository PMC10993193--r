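#' Extract steady-state activation points from a recording
#'
#' Reduces each sweep to one (temperature, current, current density) point:
#' the current is averaged over the final `window` seconds of the pulse and
#' the temperature comes from the experiment's pipette calibration table
#' (matched by laser command level) or, for synthetic recordings, optionally
#' from the stored ground-truth waveform.
#'
#' @param rec A `channel_recording`.
#' @param cal_table A `calibration_table` from [calibrate_protocol()]
#'   covering every command level in the recording (required when
#'   `temperature_source = "calibration"`).
#' @param window Averaging window at the end of each sweep, seconds
#'   (default 0.05).
#' @param temperature_source `"calibration"` (the experimental route) or
#'   `"ground_truth"` (synthetic recordings only; recorded in provenance).
#' @return A `steady_state_points` data frame with columns `command_level`,
#'   `temperature_k`, `current_pa`, `density_pa_pf`, carrying the cell
#'   metadata as attributes.
#' @export
extract_steady_state <- function(rec, cal_table = NULL, window = 0.05,
                                 temperature_source = c("calibration",
                                                        "ground_truth")) {
  stopifnot(inherits(rec, "channel_recording"))
  temperature_source <- match.arg(temperature_source)
  if (temperature_source == "calibration" &&
      !inherits(cal_table, "calibration_table")) {
    stop("a calibration_table is required when temperature_source = ",
         "\"calibration\"", call. = FALSE)
  }
  if (temperature_source == "ground_truth" &&
      length(rec$true_temperature) != length(rec$sweeps)) {
    stop("recording carries no ground-truth temperatures", call. = FALSE)
  }
  rows <- lapply(seq_along(rec$sweeps), function(i) {
    sweep <- rec$sweeps[[i]]
    t_end <- max(sweep$time_s)
    if (window <= 0 || window > t_end - min(sweep$time_s)) {
      stop("window must be positive and shorter than the sweep", call. = FALSE)
    }
    sel <- sweep$time_s >= t_end - window
    current <- mean(sweep$current_pa[sel])
    level <- attr(sweep, "command_level")
    if (temperature_source == "calibration") {
      # command levels are stimulus tags (setpoints); distinct levels differ
      # by far more than table round-off, so match with a loose tolerance
      hit <- which(abs(cal_table$command_level - level) < 1e-3)
      if (length(hit) != 1L) {
        stop(sprintf(
          "no unique calibration entry for sweep %d (command level %g)",
          i, level), call. = FALSE)
      }
      temp_k <- cal_table$temperature_k[hit]
    } else {
      tru <- rec$true_temperature[[i]]
      temp_k <- mean(tru$temperature_k[tru$time_s >= max(tru$time_s) - window])
    }
    data.frame(command_level = level, temperature_k = temp_k,
               current_pa = current,
               density_pa_pf = current / rec$metadata$capacitance_pf)
  })
  pts <- do.call(rbind, rows)
  if (nrow(pts) >= 3L && anyDuplicated(round(pts$temperature_k, 6))) {
    warning("duplicate steady-state temperatures in point set")
  }
  structure(pts,
            cell_id = rec$metadata$cell_id,
            capacitance_pf = rec$metadata$capacitance_pf,
            t_ref_k = rec$metadata$t_ref_k,
            temperature_source = temperature_source,
            class = c("steady_state_points", "data.frame"))
}

# two-state open probability parameterised by (delta_h, t_half_k);
# plogis keeps the logistic numerically stable at extreme temperatures
po_two_state <- function(temp_k, delta_h, t_half_k) {
  stats::plogis((1000 * delta_h / GAS_CONSTANT_CAL) *
                  (1 / t_half_k - 1 / temp_k))
}

#' Fit the modified Boltzmann current-density model
#'
#' Least-squares fit of the magnitude of the steady-state current density
#' against temperature with the two-component model
#' \deqn{|i|(T) = L\,a_{leak}(T) + A\,a_{i}(T)\,P_o(T;\Delta H, T_{0.5}),}
#' where `L`, `A` are leak and maximal channel densities (pA/pF) at the
#' reference temperature, \eqn{a(T)} are Arrhenius conductivity scales with
#' enthalpies `dh_leak`, `dh_i` (bounded to `[0, 15]` kcal/mol so they
#' cannot trade off against the gating enthalpy), and \eqn{P_o} is the
#' two-state open probability with parameters `delta_h` (kcal/mol) and
#' `t_half_k` (K).
#'
#' The fit is two-stage: a coarse grid over `(delta_h, T0.5)` with the leak
#' frozen at a low-temperature Arrhenius estimate and the amplitude solved
#' linearly, followed by bounded Levenberg-Marquardt refinement of all six
#' parameters ([minpack.lm::nls.lm()]) from multiple starts, keeping the
#' lowest sum of squares. Non-convergence is flagged, never silent.
#'
#' @param points A `steady_state_points` data frame (>= 6 points spanning
#'   at least 25 C).
#' @param init Optional named list of starting values overriding the
#'   automatic initialisation (`l_ref`, `dh_leak`, `a_ref`, `dh_i`,
#'   `delta_h`, `t_half_k`).
#' @param dh_cond_bounds Bounds for the conductivity enthalpies, kcal/mol.
#' @param grid_delta_h,grid_t_half_c Coarse-search grids for the gating
#'   parameters.
#' @return An object of class `boltzmann_fit` with the fitted generative
#'   parameters (`i_leak_ref`, `dh_leak`, `i_max_ref`, `dh_i`, signed with
#'   the polarity of the data), the `gating` thermodynamics, standard
#'   errors, residual norm and a convergence flag.
#' @export
fit_boltzmann_model <- function(points, init = NULL,
                                dh_cond_bounds = c(0, 15),
                                grid_delta_h = seq(20, 150, by = 5),
                                grid_t_half_c = seq(30, 70, by = 1)) {
  stopifnot(inherits(points, "steady_state_points"))
  if (nrow(points) < 6L) {
    stop("need >= 6 steady-state points to fit the Boltzmann model",
         call. = FALSE)
  }
  span <- diff(range(points$temperature_k))
  if (span < 25) {
    stop("temperature span is ", round(span, 1), " C; need >= 25 C - ",
         "extend the stimulus protocol", call. = FALSE)
  }
  t_ref_k <- attr(points, "t_ref_k")
  if (is.null(t_ref_k)) t_ref_k <- min(points$temperature_k)
  temp_k <- points$temperature_k
  polarity <- sign(points$density_pa_pf[which.max(abs(points$density_pa_pf))])
  y <- abs(points$density_pa_pf)

  # stage 1 helper: coarse grid over the gating parameters with the leak
  # frozen and the amplitude solved linearly
  grid_stage <- function(l_ref, dh_leak, dh_i) {
    leak0 <- l_ref * arrhenius_scale(dh_leak, t_ref_k, temp_k)
    resid0 <- y - leak0
    cond <- arrhenius_scale(dh_i, t_ref_k, temp_k)
    best <- list(sse = Inf)
    for (th_c in grid_t_half_c) {
      th_k <- celsius_to_kelvin(th_c)
      for (dh in grid_delta_h) {
        w <- cond * po_two_state(temp_k, dh, th_k)
        a <- max(sum(w * resid0) / sum(w * w), 0)
        sse <- sum((resid0 - a * w)^2)
        if (sse < best$sse) best <- list(sse = sse, delta_h = dh,
                                         t_half_k = th_k, a_ref = a)
      }
    }
    # floor the amplitude starts at a small fraction of the data scale:
    # exact zeros make the Jacobian singular before LM can move
    floor_amp <- 1e-3 * max(y)
    list(l_ref = max(l_ref, floor_amp), dh_leak = dh_leak,
         a_ref = max(best$a_ref, floor_amp), dh_i = dh_i,
         delta_h = best$delta_h, t_half_k = best$t_half_k, sse = best$sse)
  }

  # candidate leak initialisations: a log-Arrhenius regression on the
  # coldest points, and an electrolyte-like fallback (robust when the cold
  # tail carries no appreciable leak)
  ord <- order(temp_k)
  cold <- ord[seq_len(min(4L, nrow(points)))]
  x_cold <- 1 / t_ref_k - 1 / temp_k[cold]
  y_cold <- pmax(y[cold], 1e-12)
  leak_lm <- stats::lm(log(y_cold) ~ x_cold)
  dh_leak_fit <- min(max(unname(stats::coef(leak_lm)[2]) *
                           GAS_CONSTANT_CAL / 1000, dh_cond_bounds[1]),
                     dh_cond_bounds[2])
  dh_mid <- min(max(3.84, dh_cond_bounds[1]), dh_cond_bounds[2])
  starts <- list(
    grid_stage(exp(unname(stats::coef(leak_lm)[1])), dh_leak_fit,
               dh_leak_fit),
    grid_stage(min(y_cold), dh_mid, dh_mid)
  )
  if (!is.null(init)) {
    forced <- starts[[1]]
    forced[names(init)] <- init
    starts <- c(list(forced), starts)
  }

  # stage 2: bounded Levenberg-Marquardt refinement from each start
  lower <- c(l_ref = 0, dh_leak = dh_cond_bounds[1], a_ref = 0,
             dh_i = dh_cond_bounds[1], delta_h = 5, t_half_k = 283)
  upper <- c(l_ref = Inf, dh_leak = dh_cond_bounds[2], a_ref = Inf,
             dh_i = dh_cond_bounds[2], delta_h = 300, t_half_k = 373)
  model_fn <- function(par) {
    par["l_ref"] * arrhenius_scale(par["dh_leak"], t_ref_k, temp_k) +
      par["a_ref"] * arrhenius_scale(par["dh_i"], t_ref_k, temp_k) *
        po_two_state(temp_k, par["delta_h"], par["t_half_k"])
  }
  attempts <- lapply(starts, function(s) {
    tryCatch(
      minpack.lm::nls.lm(
        par = unlist(s[names(lower)]), lower = lower, upper = upper,
        fn = function(par) model_fn(par) - y,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)
      ),
      error = function(e) e
    )
  })
  conv <- vapply(attempts, function(a) {
    !inherits(a, "error") && a$info %in% 1:4
  }, logical(1))
  if (!any(conv)) {
    warning("Boltzmann refinement did not converge; returning coarse-grid ",
            "estimate")
    s0 <- starts[[which.min(vapply(starts, `[[`, numeric(1), "sse"))]]
    est <- unlist(s0[names(lower)])
    se <- rep(NA_real_, length(est))
    names(se) <- names(est)
    resid_norm <- sqrt(s0$sse)
    converged <- FALSE
  } else {
    sses <- vapply(attempts, function(a) {
      if (inherits(a, "error")) Inf else a$deviance
    }, numeric(1))
    sses[!conv] <- Inf
    fit <- attempts[[which.min(sses)]]
    est <- fit$par
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) {
                     s <- rep(NA_real_, length(est))
                     names(s) <- names(est)
                     s
                   })
    resid_norm <- sqrt(fit$deviance)
    converged <- TRUE
  }
  structure(
    list(
      i_leak_ref = polarity * unname(est["l_ref"]),
      dh_leak = unname(est["dh_leak"]),
      i_max_ref = polarity * unname(est["a_ref"]),
      dh_i = unname(est["dh_i"]),
      gating = gating_thermodynamics(
        unname(est["delta_h"]),
        t_half_c = kelvin_to_celsius(unname(est["t_half_k"]))),
      polarity = polarity,
      t_ref_k = t_ref_k,
      std_errors = se,
      residual_norm = resid_norm,
      converged = converged,
      n_points = nrow(points)
    ),
    class = "boltzmann_fit"
  )
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat("Modified Boltzmann current-density fit\n")
  cat(sprintf("  gating: dH = %.4g kcal/mol, T0.5 = %.2f C\n",
              x$gating$delta_h,
              kelvin_to_celsius(1000 * x$gating$delta_h / x$gating$delta_s)))
  cat(sprintf("  i_max_ref = %.4g pA/pF (dh_i = %.3g), leak = %.4g pA/pF (dh_leak = %.3g)\n",
              x$i_max_ref, x$dh_i, x$i_leak_ref, x$dh_leak))
  cat(sprintf("  residual norm %.3g over %d points; converged: %s\n",
              x$residual_norm, x$n_points, x$converged))
  invisible(x)
}

#' Leak- and conductivity-corrected open probability series
#'
#' Removes the fitted leak from the measured steady-state densities and
#' divides by the fitted temperature-dependent maximal channel density,
#' yielding the experimental open probability at each stimulus temperature:
#' \eqn{P_o(T) = (|i|(T) - L\,a_{leak}(T)) / (A\,a_i(T))}. Values outside
#' (0, 1) (noise below the leak, or above saturation) are flagged and set to
#' `NA`, never silently dropped.
#'
#' @param points The `steady_state_points` used in the fit.
#' @param fit A converged `boltzmann_fit`.
#' @return A `po_series` data frame with columns `temperature_k`, `po`,
#'   `flagged`.
#' @export
open_probability_series <- function(points, fit) {
  stopifnot(inherits(points, "steady_state_points"),
            inherits(fit, "boltzmann_fit"))
  if (!fit$converged) {
    stop("refusing to correct with a non-converged Boltzmann fit",
         call. = FALSE)
  }
  temp_k <- points$temperature_k
  y <- abs(points$density_pa_pf)
  leak <- abs(fit$i_leak_ref) * arrhenius_scale(fit$dh_leak, fit$t_ref_k, temp_k)
  gmax <- abs(fit$i_max_ref) * arrhenius_scale(fit$dh_i, fit$t_ref_k, temp_k)
  if (any(gmax <= 0)) {
    stop("fitted maximal channel density is not positive; no open ",
         "probability can be derived", call. = FALSE)
  }
  po_raw <- (y - leak) / gmax
  flagged <- po_raw <= 0 | po_raw >= 1
  po <- ifelse(flagged, NA_real_, po_raw)
  structure(
    data.frame(temperature_k = temp_k, po = po, flagged = flagged),
    n_flagged = sum(flagged),
    class = c("po_series", "data.frame")
  )
}

#' van't Hoff regression of the open probability series
#'
#' Ordinary least squares of \eqn{\ln K_{eq} = \ln(P_o/(1-P_o))} against
#' \eqn{1/T}: the slope is \eqn{-\Delta H/R} and the intercept
#' \eqn{\Delta S/R}. Because the logit diverges at the ends of the
#' probability scale, only points with `po` inside `po_window` enter the
#' regression; exclusions are counted in the result.
#'
#' @param po_series A `po_series` from [open_probability_series()].
#' @param po_window Length-2 inclusion window on the open probability
#'   (default `c(0.02, 0.98)`).
#' @return An object of class `vant_hoff_fit` with `delta_h` (kcal/mol),
#'   `delta_s` (cal/(mol K)), `r_squared`, `n_points_used`, `n_excluded`,
#'   `po_window` and the regression `points` (`inv_t_per_k`, `ln_keq`).
#' @export
vant_hoff_regression <- function(po_series, po_window = c(0.02, 0.98)) {
  stopifnot(inherits(po_series, "po_series"))
  if (length(po_window) != 2L || po_window[1] >= po_window[2] ||
      po_window[1] <= 0 || po_window[2] >= 1) {
    stop("po_window must be c(lo, hi) strictly inside (0, 1)", call. = FALSE)
  }
  usable <- !po_series$flagged & !is.na(po_series$po) &
    po_series$po >= po_window[1] & po_series$po <= po_window[2]
  if (sum(usable) < 3L) {
    stop("fewer than 3 open-probability points inside [",
         po_window[1], ", ", po_window[2], "]; widen the temperature ",
         "protocol around the activation range", call. = FALSE)
  }
  inv_t <- 1 / po_series$temperature_k[usable]
  ln_keq <- log(po_series$po[usable] / (1 - po_series$po[usable]))
  reg <- stats::lm(ln_keq ~ inv_t)
  co <- stats::coef(reg)
  structure(
    list(
      delta_h = -unname(co["inv_t"]) * GAS_CONSTANT_CAL / 1000,
      delta_s = unname(co["(Intercept)"]) * GAS_CONSTANT_CAL,
      r_squared = summary(reg)$r.squared,
      n_points_used = sum(usable),
      n_excluded = sum(!usable),
      po_window = po_window,
      points = data.frame(inv_t_per_k = inv_t, ln_keq = ln_keq)
    ),
    class = "vant_hoff_fit"
  )
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat("van't Hoff regression (ln Keq vs 1/T)\n")
  cat(sprintf("  dH = %.4g kcal/mol, dS = %.4g cal/(mol K), r2 = %.4f\n",
              x$delta_h, x$delta_s, x$r_squared))
  cat(sprintf("  %d points used, %d excluded (window %.2g-%.2g)\n",
              x$n_points_used, x$n_excluded, x$po_window[1], x$po_window[2]))
  invisible(x)
}

#' Derived activation parameters of a heat-gated channel
#'
#' From a van't Hoff (or any two-state) estimate of (dH, dS), computes the
#' characteristic temperatures T0.1 (the conventional activation
#' "threshold"), T0.5 (midpoint) and T0.9 (saturation), the temperature
#' coefficient Q10 evaluated at the midpoint, and the free-energy curve over
#' a 20-70 C grid.
#'
#' @param vh A `vant_hoff_fit`, or a [gating_thermodynamics()] object.
#' @param delta_g_grid_c Temperature grid (Celsius) for the free-energy
#'   curve.
#' @return An object of class `activation_summary`.
#' @export
derive_activation_parameters <- function(vh, delta_g_grid_c = seq(20, 70, 1)) {
  g <- if (inherits(vh, "vant_hoff_fit")) {
    gating_thermodynamics(vh$delta_h, delta_s = vh$delta_s)
  } else if (inherits(vh, "gating_thermodynamics")) {
    vh
  } else {
    stop("vh must be a vant_hoff_fit or gating_thermodynamics", call. = FALSE)
  }
  if (g$delta_h <= 0 || g$delta_s <= 0) {
    stop("activation parameters are defined for heat-activated fits ",
         "(delta_h > 0, delta_s > 0)", call. = FALSE)
  }
  t_half_k <- temperature_at_open_probability(g, 0.5)
  structure(
    list(
      delta_h = g$delta_h,
      delta_s = g$delta_s,
      t_half_c = kelvin_to_celsius(t_half_k),
      t_010_c = kelvin_to_celsius(temperature_at_open_probability(g, 0.1)),
      t_090_c = kelvin_to_celsius(temperature_at_open_probability(g, 0.9)),
      q10 = q10_factor(g, t_half_k),
      delta_g = data.frame(
        temp_c = delta_g_grid_c,
        delta_g_kcal = free_energy(g, celsius_to_kelvin(delta_g_grid_c))
      ),
      r_squared = if (inherits(vh, "vant_hoff_fit")) vh$r_squared else NA_real_,
      n_points_used = if (inherits(vh, "vant_hoff_fit")) vh$n_points_used
                      else NA_integer_
    ),
    class = "activation_summary"
  )
}

#' @export
print.activation_summary <- function(x, ...) {
  cat("Channel activation summary\n")
  cat(sprintf("  dH = %.4g kcal/mol, dS = %.4g cal/(mol K)\n",
              x$delta_h, x$delta_s))
  cat(sprintf("  T0.1 = %.1f C, T0.5 = %.1f C, T0.9 = %.1f C, Q10 = %.3g\n",
              x$t_010_c, x$t_half_c, x$t_090_c, x$q10))
  if (is.finite(x$r_squared)) {
    cat(sprintf("  van't Hoff r2 = %.4f (%d points)\n",
                x$r_squared, x$n_points_used))
  }
  invisible(x)
}

#' Aggregate per-cell activation summaries into a cohort summary
#'
#' Reports mean and standard error (SD/sqrt(n)) for each activation
#' parameter across cells, exports the per-cell (dH, dS) pairs, and fits
#' the enthalpy-entropy compensation line: regressing dH (converted to cal)
#' on dS gives a slope in Kelvin expected to approximate the cohort
#' midpoint temperature.
#'
#' @param summaries List of `activation_summary` objects, one per cell.
#' @return An object of class `cohort_summary` with elements `cells`
#'   (per-cell parameter data frame), `mean`, `sem`, `n` and
#'   `compensation_slope_k`.
#' @export
aggregate_cohort <- function(summaries) {
  if (length(summaries) < 1L) stop("need at least one cell", call. = FALSE)
  stopifnot(all(vapply(summaries, inherits, logical(1), "activation_summary")))
  cells <- do.call(rbind, lapply(seq_along(summaries), function(j) {
    s <- summaries[[j]]
    data.frame(cell = j, delta_h = s$delta_h, delta_s = s$delta_s,
               t_half_c = s$t_half_c, t_010_c = s$t_010_c,
               t_090_c = s$t_090_c, q10 = s$q10, r_squared = s$r_squared)
  }))
  n <- nrow(cells)
  pars <- c("delta_h", "delta_s", "t_half_c", "t_010_c", "t_090_c", "q10")
  means <- vapply(cells[pars], mean, numeric(1))
  if (n == 1L) {
    message("cohort of a single cell: standard errors reported as 0")
    sems <- stats::setNames(rep(0, length(pars)), pars)
  } else {
    sems <- vapply(cells[pars], function(v) stats::sd(v) / sqrt(n), numeric(1))
  }
  slope_k <- if (n >= 2L && stats::sd(cells$delta_s) > 0) {
    unname(stats::coef(stats::lm(I(1000 * delta_h) ~ delta_s,
                                 data = cells))["delta_s"])
  } else {
    NA_real_
  }
  structure(
    list(cells = cells, mean = means, sem = sems, n = n,
         compensation_slope_k = slope_k),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary (n = %d cells)\n", x$n))
  cat(sprintf("  dH   = %.4g +/- %.2g kcal/mol\n",
              x$mean["delta_h"], x$sem["delta_h"]))
  cat(sprintf("  dS   = %.4g +/- %.2g cal/(mol K)\n",
              x$mean["delta_s"], x$sem["delta_s"]))
  cat(sprintf("  T0.5 = %.2f +/- %.2g C, T0.1 = %.2f C, Q10 = %.3g\n",
              x$mean["t_half_c"], x$sem["t_half_c"],
              x$mean["t_010_c"], x$mean["q10"]))
  if (is.finite(x$compensation_slope_k)) {
    cat(sprintf("  dH-dS compensation slope = %.1f K\n",
                x$compensation_slope_k))
  }
  invisible(x)
}
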