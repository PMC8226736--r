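# Readers and writers for the delimited formats: IVPT observation
# tables, compound and vehicle parameter tables, and YAML/JSON scenario
# files. All tables are plain CSV; units are fixed package-wide
# (µg, cm, min) and converted by the caller at the boundary if needed.

.ivpt_cols <- c("compound", "solvent", "dose", "sw_mean", "sw_sd",
                "sc_mean", "sc_sd", "dd_mean", "dd_sd")
.solvent_levels <- c("pbs", "ethanol", "acetone")

#' Read an IVPT observation table
#'
#' Reads a CSV of per-experiment 24 h summaries: dose, skin wash, SC
#' accumulation and dermal delivery means and SDs (all µg/cm²). Empty
#' SD fields become `NA` (printed tables round small SDs to zero; such
#' values must be encoded as missing). Optional model prediction
#' columns (`sw_pred_a`, `sw_pred_b`, ...) are carried through when
#' present.
#'
#' @param path Path to the CSV file.
#' @return A tibble with one row per IVPT.
#' @export
#' @examples
#' read_ivpt_table(system.file("extdata", "hewitt_assessment.csv",
#'                             package = "dermavol"))
read_ivpt_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- readr::read_csv(path, col_types = readr::cols(
    compound = readr::col_character(),
    solvent = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    stop("malformed IVPT table ", path, " at line(s) ",
         paste(unique(probs$row), collapse = ", "), ": ",
         probs$expected[1], " expected, got ", probs$actual[1],
         call. = FALSE)
  }
  if (nrow(tbl) == 0) {
    warning("IVPT table ", path, " contains no records", call. = FALSE)
    return(tbl)
  }
  miss <- setdiff(.ivpt_cols, names(tbl))
  if (length(miss)) {
    stop("IVPT table ", path, " is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tbl$solvent <- tolower(tbl$solvent)
  bad <- !tbl$solvent %in% .solvent_levels
  if (any(bad)) {
    stop("unknown solvent label(s) in ", path, ": ",
         paste(unique(tbl$solvent[bad]), collapse = ", "),
         " (expected one of ", paste(.solvent_levels, collapse = ", "),
         ")", call. = FALSE)
  }
  if (any(tbl$dose <= 0, na.rm = TRUE)) {
    stop("doses must be > 0 in ", path, call. = FALSE)
  }
  means <- unlist(tbl[, c("sw_mean", "sc_mean", "dd_mean")])
  if (any(means < 0, na.rm = TRUE)) {
    stop("observed means must be >= 0 in ", path, call. = FALSE)
  }
  tbl
}

#' Write an IVPT observation table
#'
#' Inverse of [read_ivpt_table()]; missing SDs are written as empty
#' fields.
#'
#' @param data Tibble of IVPT records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ivpt_table <- function(data, path) {
  miss <- setdiff(.ivpt_cols, names(data))
  if (length(miss)) {
    stop("`data` is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(data, path, na = "")
  invisible(path)
}

#' Read a compound parameter table
#'
#' CSV with one row per compound and columns
#' `name, mw, sw, sv, ksc_w, dsc, kevap_per` (units: g/mol, µg/cm³,
#' µg/cm³, -, cm²/min, µg/cm²/min).
#'
#' @param path Path to the CSV file.
#' @return A tibble; use [as_permeant()] to turn a row into a
#'   [permeant()].
#' @export
read_compound_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- readr::read_csv(path, col_types = readr::cols(
    name = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  need <- c("name", "mw", "sw", "sv", "ksc_w", "dsc", "kevap_per")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    stop("compound table ", path, " is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tbl
}

#' Read a vehicle parameter table
#'
#' CSV with columns `name, kevap_veh, eta_dep, occluded`.
#'
#' @param path Path to the CSV file.
#' @return A tibble; use [as_vehicle_spec()] to turn a row into a
#'   [vehicle_spec()].
#' @export
read_vehicle_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- readr::read_csv(path, col_types = readr::cols(
    name = readr::col_character(), occluded = readr::col_logical(),
    .default = readr::col_double()
  ), progress = FALSE)
  need <- c("name", "kevap_veh", "eta_dep", "occluded")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) {
    stop("vehicle table ", path, " is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tbl
}

#' Coerce a compound-table row to a permeant
#'
#' @param row One-row data frame with the compound-table columns.
#' @return A [permeant()].
#' @export
as_permeant <- function(row) {
  stopifnot(nrow(row) == 1)
  permeant(row$name, mw = row$mw, sw = row$sw, sv = row$sv,
           ksc_w = row$ksc_w, dsc = row$dsc,
           kevap_per = if (is.na(row$kevap_per)) 0 else row$kevap_per)
}

#' Coerce a vehicle-table row to a vehicle specification
#'
#' @param row One-row data frame with the vehicle-table columns.
#' @return A [vehicle_spec()].
#' @export
as_vehicle_spec <- function(row) {
  stopifnot(nrow(row) == 1)
  vehicle_spec(row$name, kevap_veh = row$kevap_veh,
               eta_dep = row$eta_dep, occluded = isTRUE(row$occluded))
}

#' Read a simulation scenario file
#'
#' A YAML (or JSON) file binding a compound, a vehicle and an exposure:
#' top-level blocks `compound` (fields of [permeant()]), `vehicle`
#' (fields of [vehicle_spec()]), `exposure` (fields of
#' [exposure_scenario()]) and optional `geometry` (fields of
#' [skin_geometry()]).
#'
#' @param path Path to the YAML/JSON file.
#' @return A list with elements `permeant`, `vehicle`, `exposure`,
#'   `geometry`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (block in c("compound", "vehicle", "exposure")) {
    if (is.null(cfg[[block]])) {
      stop("scenario file ", path, " lacks the `", block, "` block",
           call. = FALSE)
    }
  }
  list(
    permeant = do.call(permeant, cfg$compound),
    vehicle = do.call(vehicle_spec, cfg$vehicle),
    exposure = do.call(exposure_scenario, cfg$exposure),
    geometry = if (is.null(cfg$geometry)) skin_geometry()
               else do.call(skin_geometry, cfg$geometry)
  )
}

#' The bundled 31-IVPT assessment table
#'
#' The bundled fixture of 24 h IVPT summaries (26 PBS and 5 ethanol
#' experiments) with both models' predictions, used for metric
#' verification throughout the package.
#'
#' @return A 31-row tibble in the [read_ivpt_table()] format plus
#'   prediction columns.
#' @export
hewitt_ivpt <- function() {
  read_ivpt_table(system.file("extdata", "hewitt_assessment.csv",
                              package = "dermavol", mustWork = TRUE))
}

#' Calibrated vehicle parameter defaults
#'
#' The calibrated wind velocities and vehicle-specific parameters
#' shipped as package defaults.
#'
#' @return A list with elements `model_a` (`u`) and `model_b`
#'   (`u`, and per-solvent `eta_dep` / `kevap_veh`).
#' @export
calibrated_parameters <- function() {
  yaml::read_yaml(system.file("extdata", "calibrated_params.yaml",
                              package = "dermavol", mustWork = TRUE))
}

#' Default vehicle specifications built from the calibrated parameters
#'
#' @param solvent `"pbs"` or `"ethanol"`.
#' @return A [vehicle_spec()] with the calibrated thinning rate and
#'   deposition-layer proportion for that solvent.
#' @export
default_vehicle <- function(solvent = c("pbs", "ethanol")) {
  solvent <- match.arg(solvent)
  p <- calibrated_parameters()$model_b[[solvent]]
  vehicle_spec(solvent, kevap_veh = p$kevap_veh, eta_dep = p$eta_dep)
}
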