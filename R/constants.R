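#' Physical constants used by the thermodynamic calculations
#'
#' Single source of truth for the universal gas constant, the Boltzmann
#' constant and Planck's constant, in the SI units the drying-thermodynamics
#' equations expect.
#'
#' @return A named list with elements `r_gas` (J mol^-1 K^-1), `k_boltzmann`
#'   (J K^-1) and `h_planck` (J s).
#' @examples
#' drying_constants()$r_gas
#' @export
drying_constants <- function() {
  list(
    r_gas = 8.314,
    k_boltzmann = 1.38e-23,
    h_planck = 6.626e-34
  )
}

# Celsius -> kelvin; kept internal so every module converts the same way.
celsius_to_kelvin <- function(temperature_c) {
  stopifnot(is.numeric(temperature_c))
  if (any(temperature_c <= -273.15)) {
    stop("temperature_c must be above absolute zero (-273.15 degC)", call. = FALSE)
  }
  temperature_c + 273.15
}
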