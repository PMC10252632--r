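#' Run the full drying-analysis pipeline
#'
#' Chains the package's stages over the synthetic fixture suite:
#' `fixtures` (generate and write the 8 runs) -> `fit` (all selected
#' thin-layer models per run) -> `diffusivity` (Fick-slab estimate per run)
#' -> `arrhenius` (regression per variety) -> `thermo` (thermodynamic
#' properties per variety and temperature) -> `compose` (proximate table)
#' -> `report` (summary JSON). Each stage writes its artifacts under
#' `out_dir` and records a content hash in `manifest.json`; rerunning with
#' unchanged configuration skips completed stages. All randomness derives
#' from `seed`, so the same configuration produces identical artifacts.
#'
#' @param config A named list (or path to a JSON file) with any of:
#'   `out_dir` (required), `seed` (default 0), `models` (default all ten),
#'   `n_terms` (default 9), `half_thickness_m` (default 0.005),
#'   `noise_sd_mr` (default 0.005), `n_starts` (default 16), `stages`
#'   (default all), `proximate_csv` (defaults to the packaged reference
#'   table), `verbose` (default TRUE).
#' @return Invisibly, the report list (also written to
#'   `out_dir/report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config), !is.null(config$out_dir))
  defaults <- list(
    seed = 0L, models = names(drying_models()), n_terms = 9L,
    half_thickness_m = 0.005, noise_sd_mr = 0.005, n_starts = 16L,
    stages = c("fixtures", "fit", "diffusivity", "arrhenius", "thermo",
               "compose", "report"),
    proximate_csv = system.file("extdata", "reference_proximate.csv",
                                package = "drykin"),
    verbose = TRUE
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  if (length(config$stages) == 0L) stop("stage list is empty", call. = FALSE)
  bad <- setdiff(config$stages, defaults$stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (m in config$models) drying_model(m) # fail fast on unknown models

  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (isTRUE(config$verbose)) message("[drykin] ", ...)

  manifest_path <- file.path(out, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else {
    list()
  }
  config_hash <- content_hash(config[c("seed", "models", "n_terms",
                                       "half_thickness_m", "noise_sd_mr",
                                       "n_starts", "proximate_csv")])
  stage_done <- function(stage, outputs) {
    identical(manifest[[stage]], config_hash) && all(file.exists(outputs))
  }
  mark_done <- function(stage) {
    manifest[[stage]] <<- config_hash
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  }

  runs <- NULL
  load_runs <- function() {
    if (is.null(runs)) {
      paths <- file.path(out, "runs", paste0(names(fixture_labels()), ".csv"))
      runs <<- lapply(paths, read_drying_run)
      names(runs) <<- names(fixture_labels())
    }
    runs
  }

  # -- fixtures ---------------------------------------------------------
  run_dir <- file.path(out, "runs")
  fixture_files <- file.path(run_dir, paste0(names(fixture_labels()), ".csv"))
  if ("fixtures" %in% config$stages && !stage_done("fixtures", fixture_files)) {
    say("fixtures: generating 8 synthetic runs (seed ", config$seed, ")")
    dir.create(run_dir, showWarnings = FALSE)
    runs <- fixture_suite(seed = config$seed, noise_sd_mr = config$noise_sd_mr)
    for (nm in names(runs)) {
      write_drying_run(runs[[nm]], file.path(run_dir, paste0(nm, ".csv")))
    }
    mark_done("fixtures")
  }

  # -- fit --------------------------------------------------------------
  fit_dir <- file.path(out, "fits")
  fit_files <- file.path(fit_dir, paste0(names(fixture_labels()), ".json"))
  if ("fit" %in% config$stages && !stage_done("fit", fit_files)) {
    say("fit: ", length(config$models), " models x 8 runs")
    dir.create(fit_dir, showWarnings = FALSE)
    for (nm in names(load_runs())) {
      fits <- fit_all_models(series_from_run(load_runs()[[nm]]),
                             models = config$models,
                             n_starts = config$n_starts, seed = config$seed + 1L)
      ranked <- rank_model_fits(fits)
      payload <- lapply(ranked, function(f) {
        f$residuals <- NULL
        unclass(f)
      })
      jsonlite::write_json(payload, file.path(fit_dir, paste0(nm, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
    mark_done("fit")
  }

  # -- diffusivity ------------------------------------------------------
  deff_file <- file.path(out, "diffusivity.json")
  if ("diffusivity" %in% config$stages && !stage_done("diffusivity", deff_file)) {
    say("diffusivity: Fick-slab estimates (", config$n_terms, " terms)")
    ests <- Map(function(r, nm) {
      e <- unclass(estimate_deff(r, half_thickness_m = config$half_thickness_m,
                                 n_terms = config$n_terms))
      e$label <- nm
      e
    }, load_runs(), names(load_runs()))
    jsonlite::write_json(ests, deff_file, auto_unbox = TRUE, digits = NA)
    mark_done("diffusivity")
  }

  # -- arrhenius --------------------------------------------------------
  arr_file <- file.path(out, "arrhenius.json")
  if ("arrhenius" %in% config$stages && !stage_done("arrhenius", arr_file)) {
    say("arrhenius: regression per variety")
    ests <- jsonlite::read_json(deff_file, simplifyVector = FALSE)
    arr <- lapply(split_by_variety(ests), function(group) {
      unclass(fit_arrhenius(
        vapply(group, `[[`, numeric(1L), "temperature_c"),
        vapply(group, `[[`, numeric(1L), "d_eff")
      ))
    })
    jsonlite::write_json(arr, arr_file, auto_unbox = TRUE, digits = NA)
    mark_done("arrhenius")
  }

  # -- thermo -----------------------------------------------------------
  thermo_file <- file.path(out, "thermo.csv")
  if ("thermo" %in% config$stages && !stage_done("thermo", thermo_file)) {
    say("thermo: enthalpy / entropy / Gibbs per variety and temperature")
    arr <- jsonlite::read_json(arr_file, simplifyVector = TRUE)
    tabs <- lapply(names(arr), function(v) {
      tp <- thermodynamic_properties(arr[[v]]$ea_kj_mol, arr[[v]]$d0,
                                     c(50, 60, 70, 80))
      cbind(variety = v, round(as.data.frame(tp), 4))
    })
    utils::write.csv(do.call(rbind, tabs), thermo_file, row.names = FALSE)
    mark_done("thermo")
  }

  # -- compose ----------------------------------------------------------
  comp_file <- file.path(out, "composition.csv")
  if ("compose" %in% config$stages && !stage_done("compose", comp_file)) {
    say("compose: proximate table from ", basename(config$proximate_csv))
    prox <- proximate_table(utils::read.csv(config$proximate_csv))
    prox$carbohydrate_pct <- round(prox$carbohydrate_pct, 2)
    prox$energy_kcal_100g <- round(prox$energy_kcal_100g, 2)
    utils::write.csv(prox, comp_file, row.names = FALSE)
    mark_done("compose")
  }

  # -- report -----------------------------------------------------------
  report <- NULL
  report_file <- file.path(out, "report.json")
  if ("report" %in% config$stages) {
    say("report: assembling summary")
    fits <- lapply(fit_files, jsonlite::read_json, simplifyVector = FALSE)
    names(fits) <- names(fixture_labels())
    ests <- jsonlite::read_json(deff_file, simplifyVector = FALSE)
    arr <- jsonlite::read_json(arr_file, simplifyVector = TRUE)
    report <- list(
      seed = config$seed,
      n_runs = length(fits),
      n_fits = sum(vapply(fits, length, integer(1L))),
      best_model = vapply(fits, function(f) f[[1L]]$model_name, character(1L)),
      d_eff = vapply(names(ests), function(nm) ests[[nm]]$d_eff, numeric(1L)),
      arrhenius = arr,
      thermo_rows = nrow(utils::read.csv(thermo_file)),
      composition_rows = nrow(utils::read.csv(comp_file))
    )
    jsonlite::write_json(report, report_file, auto_unbox = TRUE, digits = NA)
    mark_done("report")
  }
  invisible(report)
}

fixture_labels <- function() {
  labs <- as.vector(outer(c(50, 60, 70, 80), c("smelling", "pout"),
                          function(t, v) paste0(v, "_", t)))
  stats::setNames(labs, labs)
}

split_by_variety <- function(ests) {
  variety <- sub("_[0-9]+$", "", vapply(ests, `[[`, character(1L), "label"))
  split(ests, variety)
}

# Stable content hash used for stage skipping (md5 of the serialized object).
content_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
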