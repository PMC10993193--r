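#' Channel presets
#'
#' Ready-made generative cell parameter sets for the three channels whose
#' heat activation the package's analysis chain was built around:
#'
#' * `"RpTRPA5B"` — the *Rhodnius prolixus* TRPA5 channel,
#'   dH = 72.6 kcal/mol, T0.5 = 58.6 C.
#' * `"rTRPV1"` — rat TRPV1 control, dH = 88.3 kcal/mol, T0.5 = 51.6 C.
#' * `"dTRPA1D"` — fruit-fly TRPA1 isoform D control, dH = 68.7 kcal/mol,
#'   T0.5 = 53.5 C.
#'
#' The entropy is derived from the (dH, T0.5) pair as
#' `1000 * delta_h / T0.5[K]`. Generative nuisance parameters (leak density,
#' conductivity enthalpies, capacitance, noise) take the package defaults of
#' [cell_parameters()] unless overridden through `...`.
#'
#' @param name Preset name, one of `"RpTRPA5B"`, `"rTRPV1"`, `"dTRPA1D"`.
#' @param ... Overrides forwarded to [cell_parameters()].
#' @return A [cell_parameters()] object.
#' @examples
#' channel_preset("RpTRPA5B")
#' @export
channel_preset <- function(name = c("RpTRPA5B", "rTRPV1", "dTRPA1D"), ...) {
  name <- match.arg(name)
  pars <- switch(name,
    RpTRPA5B = list(delta_h = 72.6, t_half_c = 58.6),
    rTRPV1   = list(delta_h = 88.3, t_half_c = 51.6),
    dTRPA1D  = list(delta_h = 68.7, t_half_c = 53.5)
  )
  gating <- gating_thermodynamics(pars$delta_h, t_half_c = pars$t_half_c)
  cell_parameters(gating = gating, label = name, ...)
}
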