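#' Diagnostic plot of a van't Hoff regression
#'
#' ln(Keq) against 1/T with the fitted line; the slope is -dH/R and the
#' intercept dS/R.
#'
#' @param x A `vant_hoff_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.vant_hoff_fit <- function(x, ...) {
  graphics::plot(x$points$inv_t_per_k, x$points$ln_keq,
                 xlab = "1/T (1/K)", ylab = "ln Keq",
                 main = sprintf("van't Hoff: dH = %.1f kcal/mol, r2 = %.3f",
                                x$delta_h, x$r_squared), ...)
  graphics::abline(a = x$delta_s / GAS_CONSTANT_CAL,
                   b = -1000 * x$delta_h / GAS_CONSTANT_CAL, col = 2)
  invisible(x)
}

#' Diagnostic plot of a Boltzmann current-density fit
#'
#' Measured steady-state current-density magnitudes with the fitted
#' leak + channel model and the leak component alone.
#'
#' @param x A `boltzmann_fit`.
#' @param points The `steady_state_points` that produced the fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.boltzmann_fit <- function(x, points, ...) {
  temp_c <- kelvin_to_celsius(points$temperature_k)
  y <- abs(points$density_pa_pf)
  grid_k <- seq(min(points$temperature_k), max(points$temperature_k),
                length.out = 200)
  leak <- abs(x$i_leak_ref) * arrhenius_scale(x$dh_leak, x$t_ref_k, grid_k)
  model <- leak + abs(x$i_max_ref) * arrhenius_scale(x$dh_i, x$t_ref_k, grid_k) *
    open_probability(x$gating, grid_k)
  graphics::plot(temp_c, y, xlab = "Temperature (C)",
                 ylab = "|Current density| (pA/pF)",
                 main = "Modified Boltzmann fit", ...)
  graphics::lines(kelvin_to_celsius(grid_k), model, col = 2)
  graphics::lines(kelvin_to_celsius(grid_k), leak, col = 4, lty = 2)
  graphics::legend("topleft", c("data", "fit", "leak"),
                   col = c(1, 2, 4), lty = c(NA, 1, 2), pch = c(1, NA, NA),
                   bty = "n")
  invisible(x)
}
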