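#' Physical constants and unit helpers
#'
#' The molar gas constant used throughout the package, and the Celsius to
#' Kelvin conversion. All thermodynamic quantities are reported in kJ/mol
#' (enthalpy, Gibbs energy) and kJ/(K mol) (entropy); temperatures are
#' Kelvin internally and degrees Celsius at the assay-facing surface.
#'
#' @format `GAS_CONSTANT` is the molar gas constant R in J/(K mol).
#' @export
GAS_CONSTANT <- 8.314

#' @param temperature_C temperature in degrees Celsius.
#' @rdname GAS_CONSTANT
#' @export
celsius_to_kelvin <- function(temperature_C) temperature_C + 273.15

# shared validation helper: scalar positive finite number
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name),
          class = "dopatherm_invalid_value")
  }
  invisible(x)
}
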