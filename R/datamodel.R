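#' Convert moisture content from wet basis to dry basis
#'
#' Wet-basis moisture expresses water mass as a percentage of total mass;
#' dry-basis moisture expresses it as a percentage of dry-solids mass.
#' The two are related by `x_db = 100 * x_wb / (100 - x_wb)`.
#'
#' @param x_wb Moisture content, percent wet basis; values in `[0, 100)`.
#' @return Moisture content, percent dry basis. Vectorized.
#' @seealso [db_to_wb()] for the inverse.
#' @examples
#' wb_to_db(6.34) # 6.77 to two decimals
#' @export
wb_to_db <- function(x_wb) {
  stopifnot(is.numeric(x_wb))
  if (any(!is.finite(x_wb)) || any(x_wb < 0) || any(x_wb >= 100)) {
    stop("wet-basis moisture must be finite and in [0, 100)", call. = FALSE)
  }
  100 * x_wb / (100 - x_wb)
}

#' Convert moisture content from dry basis to wet basis
#'
#' Inverse of [wb_to_db()]: `x_wb = 100 * x_db / (100 + x_db)`.
#'
#' @param x_db Moisture content, percent dry basis; non-negative.
#' @return Moisture content, percent wet basis. Vectorized.
#' @examples
#' db_to_wb(wb_to_db(42)) # 42
#' @export
db_to_wb <- function(x_db) {
  stopifnot(is.numeric(x_db))
  if (any(!is.finite(x_db)) || any(x_db < 0)) {
    stop("dry-basis moisture must be finite and non-negative", call. = FALSE)
  }
  100 * x_db / (100 + x_db)
}

#' Dimensionless moisture ratio
#'
#' Normalizes a moisture content `x` between the initial (`x_i`) and
#' equilibrium (`x_e`) moisture of a drying run:
#' `MR = (x - x_e) / (x_i - x_e)`. MR is 1 at the start of drying and 0 at
#' equilibrium. Noisy data may slightly exceed `[0, 1]`; no clipping is
#' applied. All three arguments are on the same (dry) basis.
#'
#' @param x Moisture content, percent dry basis (vectorized).
#' @param x_i Initial moisture content, percent dry basis.
#' @param x_e Equilibrium moisture content, percent dry basis.
#' @return Dimensionless moisture ratio.
#' @export
moisture_ratio <- function(x, x_i, x_e) {
  stopifnot(is.numeric(x), is.numeric(x_i), is.numeric(x_e))
  if (!all(is.finite(c(x, x_i, x_e)))) {
    stop("moisture values must be finite", call. = FALSE)
  }
  if (x_i == x_e) {
    stop("degenerate normalization: initial and equilibrium moisture are equal", call. = FALSE)
  }
  if (x_i < x_e) {
    stop("initial moisture must exceed equilibrium moisture", call. = FALSE)
  }
  (x - x_e) / (x_i - x_e)
}

#' Construct a drying run
#'
#' A drying run is one temperature's gravimetric record: dry-basis moisture
#' content at a strictly increasing sequence of times starting at 0, plus the
#' metadata needed downstream (initial and equilibrium moisture for the
#' moisture ratio, slab half-thickness for diffusivity estimation).
#'
#' @param label Free-text identifier (e.g. variety name).
#' @param temperature_c Drying-air temperature, degrees Celsius.
#' @param times_min Observation times in minutes; strictly increasing,
#'   starting at 0, at least 3 points.
#' @param moisture_db Moisture content at each time, percent dry basis.
#' @param initial_moisture_db Initial moisture content, percent dry basis.
#' @param equilibrium_moisture_db Equilibrium moisture content, percent dry
#'   basis; must be non-negative and below `initial_moisture_db`.
#' @param half_thickness_m Optional slab half-thickness in metres (the
#'   characteristic dimension of the Fick-slab solution); required later by
#'   [estimate_deff()].
#' @return An object of class `drying_run`.
#' @seealso [drying_run_from_mass()], [series_from_run()]
#' @export
drying_run <- function(label, temperature_c, times_min, moisture_db,
                       initial_moisture_db, equilibrium_moisture_db,
                       half_thickness_m = NULL) {
  stopifnot(is.character(label), length(label) == 1L)
  stopifnot(is.numeric(temperature_c), length(temperature_c) == 1L)
  if (temperature_c <= -273.15) {
    stop("temperature_c must be above absolute zero", call. = FALSE)
  }
  stopifnot(is.numeric(times_min), is.numeric(moisture_db))
  if (length(times_min) != length(moisture_db)) {
    stop("times_min and moisture_db must have the same length", call. = FALSE)
  }
  if (length(times_min) < 3L) {
    stop("a drying run needs at least 3 observations", call. = FALSE)
  }
  if (!all(is.finite(times_min)) || !all(is.finite(moisture_db))) {
    stop("times and moisture values must be finite", call. = FALSE)
  }
  if (times_min[1L] != 0) {
    stop("times_min must start at 0", call. = FALSE)
  }
  if (any(diff(times_min) <= 0)) {
    stop("times_min must be strictly increasing", call. = FALSE)
  }
  stopifnot(
    is.numeric(initial_moisture_db), length(initial_moisture_db) == 1L,
    is.numeric(equilibrium_moisture_db), length(equilibrium_moisture_db) == 1L
  )
  if (!(initial_moisture_db > equilibrium_moisture_db && equilibrium_moisture_db >= 0)) {
    stop("need initial_moisture_db > equilibrium_moisture_db >= 0", call. = FALSE)
  }
  if (!is.null(half_thickness_m)) {
    stopifnot(is.numeric(half_thickness_m), length(half_thickness_m) == 1L)
    if (!is.finite(half_thickness_m) || half_thickness_m <= 0) {
      stop("half_thickness_m must be positive", call. = FALSE)
    }
  }
  structure(
    list(
      label = label,
      temperature_c = temperature_c,
      times_min = as.numeric(times_min),
      moisture_db = as.numeric(moisture_db),
      initial_moisture_db = initial_moisture_db,
      equilibrium_moisture_db = equilibrium_moisture_db,
      half_thickness_m = half_thickness_m
    ),
    class = "drying_run"
  )
}

#' Construct a drying run from sample-mass readings
#'
#' Gravimetric monitoring records total sample mass; dry-basis moisture is
#' `100 * (mass - dry_mass) / dry_mass`. The initial moisture defaults to the
#' first reading and the equilibrium moisture to the last.
#'
#' @inheritParams drying_run
#' @param mass_g Sample mass at each time, grams.
#' @param dry_mass_g Dry-solids mass, grams (from oven drying to constant
#'   mass).
#' @param initial_moisture_db,equilibrium_moisture_db Optional overrides,
#'   percent dry basis.
#' @return An object of class `drying_run`.
#' @export
drying_run_from_mass <- function(label, temperature_c, times_min, mass_g, dry_mass_g,
                                 initial_moisture_db = NULL,
                                 equilibrium_moisture_db = NULL,
                                 half_thickness_m = NULL) {
  stopifnot(is.numeric(mass_g), is.numeric(dry_mass_g), length(dry_mass_g) == 1L)
  if (!is.finite(dry_mass_g) || dry_mass_g <= 0) {
    stop("dry_mass_g must be positive", call. = FALSE)
  }
  if (any(mass_g < dry_mass_g)) {
    stop("sample mass cannot be below the dry mass", call. = FALSE)
  }
  moisture_db <- 100 * (mass_g - dry_mass_g) / dry_mass_g
  if (is.null(initial_moisture_db)) initial_moisture_db <- moisture_db[1L]
  if (is.null(equilibrium_moisture_db)) {
    equilibrium_moisture_db <- moisture_db[length(moisture_db)]
  }
  drying_run(label, temperature_c, times_min, moisture_db,
             initial_moisture_db, equilibrium_moisture_db, half_thickness_m)
}

#' Construct a moisture-ratio series
#'
#' @param times_min Observation times, minutes; strictly increasing.
#' @param mr Dimensionless moisture ratios, same length as `times_min`.
#' @return An object of class `mr_series`.
#' @seealso [series_from_run()]
#' @export
mr_series <- function(times_min, mr) {
  stopifnot(is.numeric(times_min), is.numeric(mr))
  if (length(times_min) != length(mr)) {
    stop("times_min and mr must have the same length", call. = FALSE)
  }
  if (!all(is.finite(mr)) || !all(is.finite(times_min))) {
    stop("times and moisture ratios must be finite", call. = FALSE)
  }
  if (any(diff(times_min) <= 0)) {
    stop("times_min must be strictly increasing", call. = FALSE)
  }
  structure(list(times_min = as.numeric(times_min), mr = as.numeric(mr)),
            class = "mr_series")
}

#' Moisture-ratio series of a drying run
#'
#' Applies the moisture-ratio normalization pointwise over a run's dry-basis
#' moisture record, preserving the time grid.
#'
#' @param run A [drying_run()].
#' @return An [mr_series()].
#' @export
series_from_run <- function(run) {
  stopifnot(inherits(run, "drying_run"))
  mr_series(
    run$times_min,
    moisture_ratio(run$moisture_db, run$initial_moisture_db, run$equilibrium_moisture_db)
  )
}

#' @export
print.drying_run <- function(x, ...) {
  cat(sprintf(
    "<drying_run> %s at %g degC: %d readings over %g min (Xi = %.2f, Xe = %.2f %% d.b.)\n",
    x$label, x$temperature_c, length(x$times_min), max(x$times_min),
    x$initial_moisture_db, x$equilibrium_moisture_db
  ))
  invisible(x)
}

#' @export
print.mr_series <- function(x, ...) {
  cat(sprintf("<mr_series> %d points over %g min; MR range [%.4f, %.4f]\n",
              length(x$times_min), max(x$times_min), min(x$mr), max(x$mr)))
  invisible(x)
}

#' @export
as.data.frame.mr_series <- function(x, ...) {
  data.frame(time_min = x$times_min, mr = x$mr)
}

#' @export
as.data.frame.drying_run <- function(x, ...) {
  data.frame(time_min = x$times_min, moisture_db = x$moisture_db)
}
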