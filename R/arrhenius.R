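#' Arrhenius regression of effective diffusivity on temperature
#'
#' The temperature dependence of effective moisture diffusivity is described
#' by `D_eff = D0 * exp(-Ea / (R * T))`. Linearizing with the natural
#' logarithm, `ln D_eff = ln D0 - (Ea/R) * (1/T)`, the activation energy
#' `Ea` and pre-exponential factor `D0` are obtained by ordinary least
#' squares of `ln D_eff` on `1/T` (T in kelvin).
#'
#' @param temperature_c Drying temperatures, degrees Celsius (at least 2
#'   distinct), or a data frame with columns `temperature_c` and `d_eff`
#'   (or `d_eff_m2_s`, as in [pepper_reference()]).
#' @param d_eff Effective diffusivities, m^2 s^-1, positive.
#' @return An object of class `arrhenius_fit`: list with `d0` (m^2 s^-1),
#'   `ea_kj_mol` (kJ mol^-1), `r2` and `n_points`.
#' @examples
#' fit_arrhenius(c(50, 60, 70, 80), c(5.75, 7.34, 10.62, 15.16) * 1e-10)
#' @export
fit_arrhenius <- function(temperature_c, d_eff = NULL) {
  if (is.data.frame(temperature_c)) {
    d_eff <- temperature_c$d_eff
    if (is.null(d_eff)) d_eff <- temperature_c$d_eff_m2_s
    temperature_c <- temperature_c$temperature_c
  }
  stopifnot(is.numeric(temperature_c), is.numeric(d_eff))
  if (length(temperature_c) != length(d_eff)) {
    stop("temperature_c and d_eff lengths differ", call. = FALSE)
  }
  if (length(unique(temperature_c)) < 2L) {
    stop("need at least 2 distinct temperatures", call. = FALSE)
  }
  if (any(!is.finite(d_eff)) || any(d_eff <= 0)) {
    stop("all d_eff must be positive", call. = FALSE)
  }
  inv_t <- 1 / celsius_to_kelvin(temperature_c)
  fit <- stats::lm(log(d_eff) ~ inv_t)
  r_gas <- drying_constants()$r_gas
  y <- log(d_eff)
  structure(
    list(
      d0 = exp(unname(stats::coef(fit)[1L])),
      ea_kj_mol = -unname(stats::coef(fit)[2L]) * r_gas / 1000,
      r2 = 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2),
      n_points = length(d_eff)
    ),
    class = "arrhenius_fit"
  )
}

#' Thermodynamic properties of the drying process
#'
#' From the Arrhenius parameters of moisture diffusion, computes at each
#' temperature the activated-state thermodynamic properties:
#' * enthalpy `dH = Ea - R*T` (kJ mol^-1),
#' * entropy `dS = R * (ln D0 - ln(kB/hp) - ln T)` (kJ mol^-1 K^-1),
#' * Gibbs free energy `dG = dH - T*dS` (kJ mol^-1),
#'
#' with `T` in kelvin, `kB` the Boltzmann constant and `hp` Planck's
#' constant (see [drying_constants()]). The `ln D0` term uses the numeric
#' value of `D0` in m^2 s^-1, as is conventional for this formulation.
#'
#' @param ea_kj_mol Activation energy, kJ mol^-1.
#' @param d0 Pre-exponential factor, m^2 s^-1 (positive). May also be an
#'   `arrhenius_fit`, in which case `ea_kj_mol` is ignored.
#' @param temperature_c Temperatures, degrees Celsius; vectorized.
#' @return A data frame of class `thermo_props` with columns
#'   `temperature_c`, `dh_kj_mol`, `ds_kj_mol_k`, `dg_kj_mol`.
#' @examples
#' thermodynamic_properties(31.01, 5.67e-5, c(50, 60, 70, 80))
#' @export
thermodynamic_properties <- function(ea_kj_mol, d0, temperature_c) {
  if (inherits(ea_kj_mol, "arrhenius_fit")) {
    fit <- ea_kj_mol
    if (missing(temperature_c)) temperature_c <- d0
    d0 <- fit$d0
    ea_kj_mol <- fit$ea_kj_mol
  }
  stopifnot(is.numeric(ea_kj_mol), length(ea_kj_mol) == 1L,
            is.numeric(d0), length(d0) == 1L, is.numeric(temperature_c))
  if (!is.finite(d0) || d0 <= 0) stop("d0 must be positive", call. = FALSE)
  const <- drying_constants()
  r_kj <- const$r_gas / 1000
  t_k <- celsius_to_kelvin(temperature_c)
  dh <- ea_kj_mol - r_kj * t_k
  ds <- r_kj * (log(d0) - log(const$k_boltzmann / const$h_planck) - log(t_k))
  dg <- dh - t_k * ds
  structure(
    data.frame(temperature_c = temperature_c, dh_kj_mol = dh,
               ds_kj_mol_k = ds, dg_kj_mol = dg),
    class = c("thermo_props", "data.frame")
  )
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("<arrhenius_fit> D0 = %.4g m^2/s, Ea = %.2f kJ/mol, R2 = %.4f (n = %d)\n",
              x$d0, x$ea_kj_mol, x$r2, x$n_points))
  invisible(x)
}
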