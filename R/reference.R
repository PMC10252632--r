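#' Reference values of the emulated drying study
#'
#' The package's synthetic generator emulates a convective-drying study of
#' two pepper varieties ("smelling" and "pout", whole fruits) dried at 50,
#' 60, 70 and 80 degC. The study's reported summary values are shipped as
#' plain-text reference data and are used to parameterize the generator and
#' as inputs to the downstream analysis chain:
#'
#' * `drying_summary`: drying time and equilibrium water content (wet and
#'   dry basis) per variety and temperature;
#' * `model_params`: fitted thin-layer model parameters per variety,
#'   temperature and model (long format: `param`, `value`);
#' * `diffusivity`: effective diffusivity and fit R2 per variety and
#'   temperature;
#' * `arrhenius`: pre-exponential factor, activation energy and R2 per
#'   variety;
#' * `thermo`: enthalpy, entropy and Gibbs free energy per variety and
#'   temperature;
#' * `proximate`: measured proximate constituents (dry basis) plus the
#'   reported derived carbohydrate and energy columns, per variety and
#'   treatment.
#'
#' @return A named list of data frames.
#' @examples
#' pepper_reference()$arrhenius
#' @export
pepper_reference <- function() {
  rd <- function(name) {
    utils::read.csv(system.file("extdata", name, package = "drykin",
                                mustWork = TRUE))
  }
  list(
    drying_summary = rd("reference_drying_summary.csv"),
    model_params = rd("reference_model_parameters.csv"),
    diffusivity = rd("reference_diffusivity.csv"),
    arrhenius = rd("reference_arrhenius.csv"),
    thermo = rd("reference_thermo.csv"),
    proximate = rd("reference_proximate.csv")
  )
}

#' Reference parameter vector for one model, variety and temperature
#'
#' @param variety `"smelling"` or `"pout"`.
#' @param temperature_c One of 50, 60, 70, 80.
#' @param model Model name from [drying_models()].
#' @return Named numeric vector in the model's parameter order.
#' @export
reference_model_params <- function(variety, temperature_c, model) {
  tab <- pepper_reference()$model_params
  spec <- drying_model(model)
  rows <- tab[tab$variety == variety & tab$temperature_c == temperature_c &
                tab$model == spec$name, ]
  if (nrow(rows) == 0L) {
    stop("no reference parameters for ", variety, " ", temperature_c,
         " degC, model ", model, call. = FALSE)
  }
  params <- rows$value[match(spec$param_names, rows$param)]
  if (any(is.na(params))) {
    stop("reference table is missing parameters for model ", model, call. = FALSE)
  }
  names(params) <- spec$param_names
  params
}
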