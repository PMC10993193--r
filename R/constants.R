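#' Physical constants and temperature conversions
#'
#' The package works in the calorie-based unit system used throughout the
#' thermoTRP literature: activation enthalpies in kcal/mol, entropies in
#' cal/(mol K), and the gas constant R = 1.987 cal/(mol K). Temperatures are
#' absolute (Kelvin) everywhere inside the package; Celsius appears only at
#' user-facing boundaries.
#'
#' @format `GAS_CONSTANT_CAL` is the molar gas constant in cal/(mol K);
#'   `CELSIUS_OFFSET` is the additive offset between Celsius and Kelvin.
#' @name constants
NULL

#' @rdname constants
#' @export
GAS_CONSTANT_CAL <- 1.987

#' @rdname constants
#' @export
CELSIUS_OFFSET <- 273.15

#' Convert between Celsius and Kelvin
#'
#' @param temp_c Temperature(s) in degrees Celsius.
#' @param temp_k Absolute temperature(s) in Kelvin.
#' @return Numeric vector of converted temperatures.
#' @examples
#' celsius_to_kelvin(58.6)
#' kelvin_to_celsius(331.75)
#' @export
celsius_to_kelvin <- function(temp_c) temp_c + CELSIUS_OFFSET

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(temp_k) temp_k - CELSIUS_OFFSET

# internal: validate strictly positive absolute temperatures
check_kelvin <- function(temp_k, what = "temperature") {
  if (!is.numeric(temp_k) || any(!is.finite(temp_k)) || any(temp_k <= 0)) {
    stop(what, " must be a finite absolute temperature > 0 K", call. = FALSE)
  }
  invisible(temp_k)
}
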