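#' Default progressive weighing-schedule plan
#'
#' Gravimetric drying experiments weigh frequently early, when moisture
#' changes fast, and less often later: 5-min steps for the first hour, then
#' 10-, 15-, 20-, 30- and 40-min steps for one hour each, then 60-min steps
#' until the run ends.
#'
#' @return A data frame with columns `interval_min` and `duration_min`; the
#'   last row's duration is `Inf` (the open-ended tail).
#' @export
drying_schedule_plan <- function() {
  data.frame(
    interval_min = c(5, 10, 15, 20, 30, 40, 60),
    duration_min = c(60, 60, 60, 60, 60, 60, Inf)
  )
}

#' Build a weighing-time sequence from an interval plan
#'
#' @param total_time_min Required span in minutes (positive); the schedule
#'   ends at the first time at or beyond it.
#' @param plan Interval plan as in [drying_schedule_plan()].
#' @return Times in minutes, starting at 0, strictly increasing, with
#'   consecutive differences equal to the plan's intervals.
#' @examples
#' make_schedule(20) # 0, 5, 10, 15, 20
#' @export
make_schedule <- function(total_time_min, plan = drying_schedule_plan()) {
  stopifnot(is.numeric(total_time_min), length(total_time_min) == 1L)
  if (!is.finite(total_time_min) || total_time_min <= 0) {
    stop("total_time_min must be positive", call. = FALSE)
  }
  if (!is.data.frame(plan) || nrow(plan) == 0L ||
      !all(c("interval_min", "duration_min") %in% names(plan))) {
    stop("plan must be a non-empty data frame with interval_min and duration_min",
         call. = FALSE)
  }
  if (any(plan$interval_min <= 0) || any(plan$duration_min <= 0)) {
    stop("plan intervals and durations must be positive", call. = FALSE)
  }
  if (!is.infinite(plan$duration_min[nrow(plan)])) {
    stop("the last plan block must be open-ended (duration Inf)", call. = FALSE)
  }
  times <- 0
  t <- 0
  for (i in seq_len(nrow(plan))) {
    block_end <- t + plan$duration_min[i]
    while (t < block_end && t < total_time_min) {
      t <- t + plan$interval_min[i]
      times <- c(times, t)
    }
    if (t >= total_time_min) break
  }
  times
}

#' Configuration for a synthetic drying run
#'
#' Describes how to emulate one gravimetric drying experiment: a generating
#' moisture-ratio curve (a thin-layer model at given parameters, or the
#' Fick-slab series at a given diffusivity), the drying conditions, the
#' weighing schedule, a noise level and an equilibrium-detection rule.
#'
#' @param generator Either `thinlayer_generator(model, params)` or
#'   `slab_generator(d_eff, half_thickness_m, n_terms)`.
#' @param temperature_c Drying temperature, degC.
#' @param initial_moisture_db Initial moisture, percent dry basis.
#' @param equilibrium_moisture_db Equilibrium moisture, percent dry basis.
#' @param label Run label.
#' @param schedule_plan Weighing plan, see [drying_schedule_plan()].
#' @param noise_sd_mr Standard deviation of additive Gaussian noise on the
#'   moisture ratio (default 0.005, consistent with the fit RMSDs of typical
#'   thin-layer experiments). Noise is truncated by resampling to
#'   (-0.05, 1.05), additionally floored so dry-basis moisture stays
#'   non-negative.
#' @param stop_delta_db Equilibrium threshold: the run ends at the first
#'   reading where the noise-free dry-basis moisture change since the
#'   previous reading falls below this (default 5 percent d.b. per reading;
#'   see the package vignette).
#' @param half_thickness_m Slab half-thickness recorded on the run, metres.
#' @param seed Integer seed; same seed, same run.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(generator, temperature_c, initial_moisture_db,
                             equilibrium_moisture_db, label = "synthetic",
                             schedule_plan = drying_schedule_plan(),
                             noise_sd_mr = 0.005, stop_delta_db = 5,
                             half_thickness_m = 0.005, seed = 1L) {
  stopifnot(is.list(generator), !is.null(generator$type))
  stopifnot(noise_sd_mr >= 0, stop_delta_db > 0)
  if (!(initial_moisture_db > equilibrium_moisture_db &&
        equilibrium_moisture_db >= 0)) {
    stop("need initial_moisture_db > equilibrium_moisture_db >= 0", call. = FALSE)
  }
  structure(
    list(generator = generator, temperature_c = temperature_c,
         initial_moisture_db = initial_moisture_db,
         equilibrium_moisture_db = equilibrium_moisture_db, label = label,
         schedule_plan = schedule_plan, noise_sd_mr = noise_sd_mr,
         stop_delta_db = stop_delta_db, half_thickness_m = half_thickness_m,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' @rdname synthetic_config
#' @param model,params Thin-layer model name and parameter vector.
#' @export
thinlayer_generator <- function(model, params) {
  spec <- drying_model(model)
  stopifnot(length(params) == length(spec$param_names))
  list(type = "thinlayer", model = spec$name, params = as.numeric(params))
}

#' @rdname synthetic_config
#' @param d_eff Effective diffusivity of the slab generator, m^2 s^-1.
#' @param n_terms Series terms for the slab generator.
#' @export
slab_generator <- function(d_eff, half_thickness_m, n_terms = 9L) {
  stopifnot(d_eff > 0, half_thickness_m > 0)
  list(type = "slab", d_eff = d_eff, half_thickness_m = half_thickness_m,
       n_terms = as.integer(n_terms))
}

generator_mr <- function(generator, times_min) {
  switch(generator$type,
    thinlayer = eval_drying_model(generator$model, generator$params, times_min),
    slab = slab_mr(generator$d_eff, generator$half_thickness_m,
                   times_min * 60, generator$n_terms),
    stop("unknown generator type '", generator$type, "'", call. = FALSE)
  )
}

#' Simulate a gravimetric drying run
#'
#' Evaluates the configured moisture-ratio curve on the progressive weighing
#' schedule, truncates the run at the equilibrium (constant-mass) criterion
#' applied to the noise-free trajectory, maps the ratio back to dry-basis
#' moisture and adds truncated Gaussian measurement noise. Deterministic for
#' a given seed.
#'
#' @param config A [synthetic_config()].
#' @return A [drying_run()].
#' @export
simulate_run <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cap_min <- 1e5
  times <- make_schedule(cap_min, config$schedule_plan)
  mr_true <- generator_mr(config$generator, times)
  x_i <- config$initial_moisture_db
  x_e <- config$equilibrium_moisture_db
  x_true <- x_e + mr_true * (x_i - x_e)
  delta <- abs(diff(x_true))
  stop_idx <- which(delta < config$stop_delta_db)
  stop_idx <- stop_idx[stop_idx > 1L] # never stop on the first interval
  if (length(stop_idx) == 0L) {
    stop("equilibrium not reached within ", cap_min, " min", call. = FALSE)
  }
  keep <- seq_len(stop_idx[1L] + 1L)
  times <- times[keep]
  mr_obs <- mr_true[keep]

  if (config$noise_sd_mr > 0) {
    lo <- max(-0.05, -x_e / (x_i - x_e))
    hi <- 1.05
    mr_obs <- withr::with_seed(config$seed, {
      out <- mr_obs + stats::rnorm(length(mr_obs), sd = config$noise_sd_mr)
      bad <- which(out <= lo | out >= hi)
      while (length(bad) > 0L) {
        out[bad] <- mr_true[bad] + stats::rnorm(length(bad), sd = config$noise_sd_mr)
        bad <- bad[out[bad] <= lo | out[bad] >= hi]
      }
      out
    })
  }
  drying_run(
    label = config$label,
    temperature_c = config$temperature_c,
    times_min = times,
    moisture_db = x_e + mr_obs * (x_i - x_e),
    initial_moisture_db = x_i,
    equilibrium_moisture_db = x_e,
    half_thickness_m = config$half_thickness_m
  )
}

#' Synthetic fixture suite emulating the reference study design
#'
#' Eight runs (2 varieties x 4 temperatures), each generated from the
#' Midilli curve at the reference fitted parameters
#' ([pepper_reference()]`$model_params`), with initial moisture from the
#' in natura water content, equilibrium moisture from the reference drying
#' summary, an assumed slab half-thickness of 0.005 m (the study does not
#' report sample thickness) and the default noise level. Deterministic for a
#' given seed.
#'
#' @param seed Base integer seed; each run derives its own seed from it.
#' @param noise_sd_mr Noise level on the moisture ratio.
#' @return A named list of 8 [drying_run()] objects
#'   (`smelling_50` ... `pout_80`).
#' @export
fixture_suite <- function(seed = 0L, noise_sd_mr = 0.005) {
  ref <- pepper_reference()
  init_wb <- c(smelling = 91.88, pout = 83.30)
  runs <- list()
  i <- 0L
  for (variety in c("smelling", "pout")) {
    for (temp in c(50, 60, 70, 80)) {
      i <- i + 1L
      row <- ref$drying_summary[ref$drying_summary$variety == variety &
                                  ref$drying_summary$temperature_c == temp, ]
      cfg <- synthetic_config(
        generator = thinlayer_generator(
          "midilli", reference_model_params(variety, temp, "midilli")
        ),
        temperature_c = temp,
        initial_moisture_db = wb_to_db(init_wb[[variety]]),
        equilibrium_moisture_db = row$water_db_pct,
        label = paste0(variety, "_", temp),
        noise_sd_mr = noise_sd_mr,
        half_thickness_m = 0.005,
        seed = (abs(seed) %% 1000000L) * 1000L + i
      )
      runs[[cfg$label]] <- simulate_run(cfg)
    }
  }
  runs
}
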