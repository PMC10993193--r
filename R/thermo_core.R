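#' Two-state gating thermodynamics
#'
#' A heat-activated channel is modelled as a closed/open two-state system
#' whose equilibrium constant follows the van't Hoff relation
#' \deqn{\ln K_{eq}(T) = -\Delta H/(R T) + \Delta S/R,}
#' with the activation enthalpy \eqn{\Delta H} in kcal/mol and the activation
#' entropy \eqn{\Delta S} in cal/(mol K). For a heat-activated channel both
#' are positive, the open probability \eqn{P_o = K_{eq}/(1+K_{eq})} rises
#' monotonically with temperature, and the midpoint temperature at which half
#' the channels are open is \eqn{T_{0.5} = 1000\,\Delta H/\Delta S} (Kelvin).
#'
#' The kcal-to-cal factor of 1000 is applied exactly once, inside this
#' module, so every printed quantity keeps the units used in the
#' electrophysiology literature.
#'
#' @param delta_h Activation enthalpy change of the closed-to-open
#'   transition, kcal/mol. Positive for heat-activated channels.
#' @param delta_s Activation entropy change, cal/(mol K). Exactly one of
#'   `delta_s` and `t_half_c` must be given.
#' @param t_half_c Optional midpoint temperature in degrees Celsius; when
#'   given, `delta_s` is derived as `1000 * delta_h / (t_half_c + 273.15)`.
#' @return An object of class `gating_thermodynamics` with fields `delta_h`
#'   and `delta_s`.
#' @examples
#' g <- gating_thermodynamics(delta_h = 72.6, t_half_c = 58.6)
#' open_probability(g, celsius_to_kelvin(58.6))
#' q10_factor(g, celsius_to_kelvin(58.6))
#' @seealso [equilibrium_constant()], [open_probability()],
#'   [temperature_at_open_probability()], [q10_factor()], [free_energy()]
#' @export
gating_thermodynamics <- function(delta_h, delta_s = NULL, t_half_c = NULL) {
  if (!is.numeric(delta_h) || length(delta_h) != 1L || !is.finite(delta_h)) {
    stop("delta_h must be a single finite number (kcal/mol)", call. = FALSE)
  }
  if (is.null(delta_s) == is.null(t_half_c)) {
    stop("supply exactly one of delta_s or t_half_c", call. = FALSE)
  }
  if (is.null(delta_s)) {
    t_half_k <- celsius_to_kelvin(t_half_c)
    check_kelvin(t_half_k, "t_half_c (converted to Kelvin)")
    delta_s <- 1000 * delta_h / t_half_k
  }
  if (!is.numeric(delta_s) || length(delta_s) != 1L || !is.finite(delta_s)) {
    stop("delta_s must be a single finite number (cal/(mol K))", call. = FALSE)
  }
  structure(
    list(delta_h = delta_h, delta_s = delta_s),
    class = "gating_thermodynamics"
  )
}

#' @export
print.gating_thermodynamics <- function(x, ...) {
  cat("Two-state gating thermodynamics\n")
  cat(sprintf("  dH    = %.4g kcal/mol\n", x$delta_h))
  cat(sprintf("  dS    = %.4g cal/(mol K)\n", x$delta_s))
  if (x$delta_h > 0 && x$delta_s > 0) {
    t_half <- 1000 * x$delta_h / x$delta_s
    cat(sprintf("  T0.5  = %.2f K (%.2f C)\n", t_half, kelvin_to_celsius(t_half)))
    cat(sprintf("  Q10   = %.3g at T0.5\n", q10_factor(x, t_half)))
  }
  invisible(x)
}

#' Equilibrium constant of the closed-open transition
#'
#' Evaluates \eqn{K_{eq}(T) = \exp(-1000\,\Delta H/(R T) + \Delta S/R)}.
#'
#' @param g A [gating_thermodynamics()] object.
#' @param temp_k Absolute temperature(s), Kelvin (> 0).
#' @return Dimensionless equilibrium constant(s), strictly positive and
#'   strictly increasing in temperature when `delta_h > 0`.
#' @examples
#' g <- gating_thermodynamics(72.6, t_half_c = 58.6)
#' equilibrium_constant(g, 341.75)  # ~25.1
#' @export
equilibrium_constant <- function(g, temp_k) {
  stopifnot(inherits(g, "gating_thermodynamics"))
  check_kelvin(temp_k)
  exp(-1000 * g$delta_h / (GAS_CONSTANT_CAL * temp_k) +
        g$delta_s / GAS_CONSTANT_CAL)
}

#' Open probability at a given temperature
#'
#' \eqn{P_o(T) = K_{eq}/(1+K_{eq}) = 1/(1+\exp(\Delta G/(RT)))}, with
#' \eqn{\Delta G = \Delta H - T \Delta S}. At the midpoint temperature
#' \eqn{T_{0.5}} the free energy vanishes and \eqn{P_o = 0.5} exactly.
#'
#' @inheritParams equilibrium_constant
#' @return Open probability in (0, 1); strictly increasing in temperature
#'   for heat-activated parameters.
#' @export
open_probability <- function(g, temp_k) {
  keq <- equilibrium_constant(g, temp_k)
  keq / (1 + keq)
}

#' Temperature at which a given open probability is reached
#'
#' Algebraic inversion of the two-state model:
#' \deqn{T(p) = \frac{1000\,\Delta H}{\Delta S - R \ln(p/(1-p))}.}
#' `p = 0.5` gives the midpoint `1000 delta_h / delta_s`; `p = 0.1` gives the
#' conventional activation "threshold" temperature.
#'
#' @inheritParams equilibrium_constant
#' @param p Open probability, strictly inside (0, 1).
#' @return Absolute temperature(s) in Kelvin satisfying
#'   `open_probability(g, T) == p` to machine precision.
#' @export
temperature_at_open_probability <- function(g, p) {
  stopifnot(inherits(g, "gating_thermodynamics"))
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("p must lie strictly inside (0, 1)", call. = FALSE)
  }
  denom <- g$delta_s - GAS_CONSTANT_CAL * log(p / (1 - p))
  if (any(denom <= 0)) {
    stop("no finite positive temperature reaches this open probability ",
         "for the given entropy", call. = FALSE)
  }
  1000 * g$delta_h / denom
}

#' Temperature coefficient Q10
#'
#' Fold change of the equilibrium constant over a 10 K interval starting at
#' `temp_k`:
#' \deqn{Q_{10}(T) = \frac{K_{eq}(T+10)}{K_{eq}(T)}
#'   = \exp\left(\frac{1000\,\Delta H}{R}\cdot\frac{10}{T (T+10)}\right).}
#' Values far above ~3 are the hallmark of thermoTRP channels.
#'
#' @inheritParams equilibrium_constant
#' @return Dimensionless fold change; > 1 for `delta_h > 0` and decreasing
#'   in temperature.
#' @export
q10_factor <- function(g, temp_k) {
  stopifnot(inherits(g, "gating_thermodynamics"))
  check_kelvin(temp_k)
  exp((1000 * g$delta_h / GAS_CONSTANT_CAL) * 10 / (temp_k * (temp_k + 10)))
}

#' Gibbs free energy of the closed-open transition
#'
#' \eqn{\Delta G(T) = \Delta H - T\,\Delta S/1000 = -R T \ln K_{eq}/1000},
#' reported in kcal/mol. Zero at the midpoint temperature; small magnitudes
#' over the physiological range despite the large enthalpy and entropy, the
#' enthalpy-entropy compensation typical of thermoTRP gating.
#'
#' @inheritParams equilibrium_constant
#' @return Free energy change(s), kcal/mol.
#' @export
free_energy <- function(g, temp_k) {
  stopifnot(inherits(g, "gating_thermodynamics"))
  check_kelvin(temp_k)
  g$delta_h - temp_k * g$delta_s / 1000
}
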