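#' Write a drying run to CSV with a JSON metadata sidecar
#'
#' The CSV holds the time series with columns `time_min` and `moisture_db`;
#' the run metadata (label, temperature, initial/equilibrium moisture,
#' half-thickness) goes to a JSON sidecar at the same path with the extension
#' replaced by `.json`.
#'
#' @param run A [drying_run()].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @seealso [read_drying_run()]
#' @export
write_drying_run <- function(run, path) {
  stopifnot(inherits(run, "drying_run"))
  utils::write.csv(as.data.frame(run), path, row.names = FALSE)
  meta <- run[c("label", "temperature_c", "initial_moisture_db",
                "equilibrium_moisture_db", "half_thickness_m")]
  meta <- meta[!vapply(meta, is.null, logical(1L))]
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a drying run written by [write_drying_run()]
#'
#' Expects a CSV with columns `time_min` and either `moisture_db` or `mass_g`
#' (the latter requires `dry_mass_g` in the sidecar), plus the JSON sidecar
#' with fields `label`, `temperature_c`, `initial_moisture_db`,
#' `equilibrium_moisture_db` and optionally `half_thickness_m`.
#'
#' @param path CSV file path.
#' @return A [drying_run()].
#' @export
read_drying_run <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  side <- sidecar_path(path)
  if (!file.exists(side)) {
    stop("missing JSON metadata sidecar: ", side, call. = FALSE)
  }
  dat <- utils::read.csv(path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (!"time_min" %in% names(dat)) {
    stop("drying-run CSV must have a 'time_min' column", call. = FALSE)
  }
  for (field in c("label", "temperature_c", "initial_moisture_db", "equilibrium_moisture_db")) {
    if (is.null(meta[[field]])) {
      stop("sidecar is missing required field '", field, "'", call. = FALSE)
    }
  }
  half <- meta$half_thickness_m
  if ("moisture_db" %in% names(dat)) {
    drying_run(meta$label, meta$temperature_c, dat$time_min, dat$moisture_db,
               meta$initial_moisture_db, meta$equilibrium_moisture_db, half)
  } else if ("mass_g" %in% names(dat)) {
    if (is.null(meta$dry_mass_g)) {
      stop("mass-based CSV needs 'dry_mass_g' in the sidecar", call. = FALSE)
    }
    drying_run_from_mass(meta$label, meta$temperature_c, dat$time_min, dat$mass_g,
                         meta$dry_mass_g, meta$initial_moisture_db,
                         meta$equilibrium_moisture_db, half)
  } else {
    stop("drying-run CSV must have a 'moisture_db' or 'mass_g' column", call. = FALSE)
  }
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}
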