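# CSV/JSON readers and writers for the pipeline's tables. All files carry
# the field's customary units in their column names (um, m, MPa, mPa*s, ns,
# s); conversion to SI happens only inside the computational modules.
# Empty cells are missing values; a missing plate thickness triggers the
# documented default (with a warning) downstream in conductivity_table().

ELEMENT_COLUMNS <- c("element_id", "plant_id", "position_m", "phloem_type",
                     "se_radius_um", "se_length_um", "plate_thickness_um",
                     "pore_count")
PORE_COLUMNS <- c("element_id", "pore_radius_um")
TURGOR_COLUMNS <- c("site", "pressure_MPa")
CALIBRATION_COLUMNS <- c("eta_mPas", "tau_ns")
TRACE_COLUMNS <- c("time_s", "counts")

check_columns <- function(df, required, what) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    schema_error(sprintf("%s table lacks column(s): %s", what,
                         paste(missing_cols, collapse = ", ")))
  }
  invisible(df)
}

# positive-value check reporting 1-based data row numbers
check_rows_positive <- function(df, col, what, strict = TRUE) {
  x <- df[[col]]
  bad <- if (strict) which(!is.na(x) & x <= 0) else which(!is.na(x) & x < 0)
  if (length(bad) > 0) {
    schema_error(sprintf("%s: non-positive '%s' in row(s) %s", what, col,
                         paste(utils::head(bad, 5), collapse = ", ")))
  }
  na <- which(is.na(x))
  if (strict && length(na) > 0) {
    schema_error(sprintf("%s: missing '%s' in row(s) %s", what, col,
                         paste(utils::head(na, 5), collapse = ", ")))
  }
  invisible(df)
}

validate_elements <- function(df, what = "element") {
  if (!is.data.frame(df) || nrow(df) == 0) {
    schema_error(sprintf("%s table is empty or not a data frame", what))
  }
  check_columns(df, ELEMENT_COLUMNS, what)
  if (anyDuplicated(df$element_id)) {
    schema_error(sprintf("%s: duplicated element_id in row(s) %s", what,
                         paste(utils::head(which(duplicated(df$element_id)), 5),
                               collapse = ", ")))
  }
  for (col in c("se_radius_um", "se_length_um", "pore_count")) {
    check_rows_positive(df, col, what)
  }
  check_rows_positive(df, "plate_thickness_um", what, strict = FALSE)
  bad_type <- which(!df$phloem_type %in% c("internal", "external"))
  if (length(bad_type) > 0) {
    schema_error(sprintf("%s: phloem_type must be 'internal' or 'external' in row(s) %s",
                         what, paste(utils::head(bad_type, 5), collapse = ", ")))
  }
  df
}

validate_pores <- function(df, what = "pore") {
  if (!is.data.frame(df) || nrow(df) == 0) {
    schema_error(sprintf("%s table is empty or not a data frame", what))
  }
  check_columns(df, PORE_COLUMNS, what)
  check_rows_positive(df, "pore_radius_um", what)
  df
}

read_csv_checked <- function(path, what) {
  if (!file.exists(path)) schema_error(sprintf("%s file not found: %s", what, path))
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) schema_error(sprintf("cannot parse %s file %s: %s",
                                                          what, path, conditionMessage(e))))
  if (nrow(df) == 0) schema_error(sprintf("%s file %s has no data rows", what, path))
  df
}

#' Read sieve-tube geometry tables
#'
#' @param elements_path CSV of per-element measurements (columns
#'   `element_id`, `plant_id`, `position_m`, `phloem_type`, `se_radius_um`,
#'   `se_length_um`, `plate_thickness_um`, `pore_count`, optionally
#'   `mean_pore_radius_um`).
#' @param pores_path Optional companion per-pore CSV (`element_id`,
#'   `pore_radius_um`).
#' @return List with `elements` and `pores` (NULL when not supplied).
#' @export
read_geometry <- function(elements_path, pores_path = NULL) {
  elements <- validate_elements(read_csv_checked(elements_path, "element"))
  pores <- if (!is.null(pores_path)) {
    validate_pores(read_csv_checked(pores_path, "pore"))
  }
  list(elements = elements, pores = pores)
}

#' Write sieve-tube geometry tables
#'
#' @param geom List with `elements` and optionally `pores` (as from
#'   [gen_geometry()]).
#' @param elements_path,pores_path Output CSV paths.
#' @return Invisibly, the paths written.
#' @export
write_geometry <- function(geom, elements_path, pores_path = NULL) {
  utils::write.csv(geom$elements, elements_path, row.names = FALSE)
  if (!is.null(pores_path) && !is.null(geom$pores)) {
    utils::write.csv(geom$pores, pores_path, row.names = FALSE)
  }
  invisible(c(elements_path, pores_path))
}

#' Read a turgor-pressure table
#' @param path CSV with columns `site`, `pressure_MPa` (extra columns kept).
#' @return Data frame.
#' @export
read_turgor <- function(path) {
  df <- read_csv_checked(path, "turgor")
  check_columns(df, TURGOR_COLUMNS, "turgor")
  check_rows_positive(df, "pressure_MPa", "turgor")
  df
}

#' Read rotor calibration points
#' @param path CSV with columns `eta_mPas`, `tau_ns` (optional `sd_ns`, `n`).
#' @return Data frame.
#' @export
read_calibration <- function(path) {
  df <- read_csv_checked(path, "calibration")
  check_columns(df, CALIBRATION_COLUMNS, "calibration")
  check_rows_positive(df, "eta_mPas", "calibration")
  check_rows_positive(df, "tau_ns", "calibration")
  df
}

#' Read a detector trace
#' @param path CSV with columns `time_s`, `counts`.
#' @param position Detector position along the stem, m.
#' @return A [detector_trace()].
#' @export
read_trace <- function(path, position) {
  df <- read_csv_checked(path, "trace")
  check_columns(df, TRACE_COLUMNS, "trace")
  detector_trace(position, df$time_s, df$counts)
}

#' Write a detector trace
#' @param trace A [detector_trace()].
#' @param path Output CSV path.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(data.frame(time_s = trace$times, counts = trace$counts),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a plant scenario from JSON
#'
#' Expected fields: `source_turgors`, `sink_turgors` (arrays, MPa),
#' `transport_length` (m), `velocity` (um/s), `viscosity` (mPa*s),
#' `conductivity` (um^2).
#'
#' @param path JSON file path.
#' @return A [plant_scenario()].
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) config_error(sprintf("scenario file not found: %s", path))
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("source_turgors", "sink_turgors", "transport_length",
            "velocity", "viscosity", "conductivity")
  missing_fields <- setdiff(need, names(js))
  if (length(missing_fields) > 0) {
    config_error(sprintf("scenario lacks field(s): %s",
                         paste(missing_fields, collapse = ", ")))
  }
  plant_scenario(js$source_turgors, js$sink_turgors, js$transport_length,
                 js$velocity, js$viscosity, js$conductivity)
}

#' Write any result object as JSON
#' @param x A list-like result (e.g. a `feasibility_report` or
#'   `rotor_calibration`).
#' @param path Output path.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
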