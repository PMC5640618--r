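# Physical constants and run configuration.
#
# The constants table mirrors the parameter summary of the box model: every
# entry carries units and an error semantic (standard_error for sample
# means, standard_deviation for single measurements, range for scenario
# bounds, fixed for adopted values).

.error_types <- c("standard_error", "standard_deviation", "range", "fixed")

.constant_row <- function(name, value, units, error = NA_real_,
                          error_type = "fixed", note = "") {
  data.frame(name = name, value = value, units = units, error = error,
             error_type = error_type, note = note,
             stringsAsFactors = FALSE)
}

#' Default physical constants of the CO2 triple-oxygen budget
#'
#' Returns the full set of constants the package computes with: the
#' three-isotope exponents, water-CO2 fractionation factors, water and CO2
#' endmember anomalies (both conventions), carbon fluxes, the stratospheric
#' isoflux, the atmospheric CO2 mass loading, and the plant-uptake scenario
#' bounds. Each constant carries its units and an error semantic so that
#' uncertainty propagation can distinguish standard errors of sample means
#' from single-measurement standard deviations.
#'
#' @return a `data.frame` with columns `name`, `value`, `units`, `error`,
#'   `error_type` and `note`, one row per constant.
#' @seealso [constants_list()], [read_constants()], [write_constants()]
#' @export
default_constants <- function() {
  rbind(
    .constant_row("lambda_0", 0.516, "-", NA, "fixed",
                  "reference three-isotope exponent"),
    .constant_row("lambda_water_co2", 0.5229, "-", NA, "fixed",
                  "water-CO2 equilibration exponent"),
    .constant_row("lambda_meteoric", 0.528, "-", NA, "fixed",
                  "meteoric water line exponent"),
    .constant_row("lambda_diff", 0.5185, "-", NA, "fixed",
                  "diffusion exponent"),
    .constant_row("lambda_trans", 0.516, "-", 0.004, "standard_error",
                  "transpiration exponent at RH = 75 +/- 5%"),
    .constant_row("rh", 0.75, "fraction", 0.05, "standard_error",
                  "globally averaged near-surface relative humidity"),
    .constant_row("rh_sensitivity", 0.015, "permil per 0.05 RH", NA, "fixed",
                  "anomaly shift of leaf-equilibrated CO2 per RH deviation"),
    .constant_row("rh_sensitivity_error", 0.017, "permil per 0.05 RH", NA,
                  "fixed", "transpiration term used in the error budget"),
    .constant_row("alpha18_land", 1.043, "-", NA, "fixed",
                  "18O water-CO2 fractionation at 15 C (land)"),
    .constant_row("alpha18_ocean", 1.042, "-", NA, "fixed",
                  "18O water-CO2 fractionation at 20 C (ocean)"),
    .constant_row("cap17_meteoric_water", -0.046, "permil", 0.005,
                  "standard_error", "meteoric water anomaly, lambda = 0.516"),
    .constant_row("d18_meteoric_water", -6.5, "permil", NA, "fixed",
                  "assumed mean meteoric water d18O for lambda rescaling"),
    .constant_row("cap17_ocean_water", 0.000, "permil", 0.001,
                  "standard_error", "ocean water anomaly, lambda = 0.516"),
    .constant_row("d18_ocean_water", 0.42, "permil", NA, "fixed",
                  "assumed mean ocean water d18O for lambda rescaling"),
    .constant_row("cap17_anthropogenic", -0.21, "permil", NA, "fixed",
                  "combustion CO2 anomaly, inherits air O2"),
    .constant_row("delta_leaf", -0.009, "permil", 0.006, "standard_error",
                  "leaf CO2, linear convention"),
    .constant_row("delta_respiration", 0.019, "permil", 0.006,
                  "standard_error", "respired CO2, linear convention"),
    .constant_row("delta_soil", 0.019, "permil", 0.006, "standard_error",
                  "soil-invasion CO2, linear convention"),
    .constant_row("delta_ocean", 0.075, "permil", 0.001, "standard_error",
                  "oceanic CO2, linear convention"),
    .constant_row("delta_anthropogenic", -0.286, "permil", 0.001,
                  "standard_error", "anthropogenic CO2, linear convention"),
    .constant_row("d18_leaf_co2", 46.2, "permil", NA, "fixed",
                  "assumed d18O of leaf CO2 (reverse-engineered)"),
    .constant_row("d18_soil_co2", 43.6, "permil", NA, "fixed",
                  "assumed d18O of soil/respired CO2 (reverse-engineered)"),
    .constant_row("d18_ocean_co2", 42.0, "permil", NA, "fixed",
                  "assumed d18O of oceanic CO2"),
    .constant_row("d18_anthropogenic_co2", 24.5, "permil", NA, "fixed",
                  "assumed d18O of anthropogenic CO2 (reverse-engineered)"),
    .constant_row("cap17_atmosphere", 0.326, "permil", 0.005,
                  "standard_error", "tropospheric CO2 anomaly, 4-site mean"),
    .constant_row("cap17_atmosphere_sd", 0.039, "permil", 0.039,
                  "standard_deviation", "single-measurement spread (Taipei)"),
    .constant_row("d18_atmosphere", 41.0, "permil", NA, "fixed",
                  "tropospheric CO2 d18O used for convention conversion"),
    .constant_row("f_ao", 90, "PgC/yr", 6, "standard_error",
                  "gross air-to-ocean CO2 flux"),
    .constant_row("f_anth", 9.4, "PgC/yr", 0.8, "standard_error",
                  "anthropogenic CO2 flux (2011)"),
    .constant_row("strat_isoflux", 50, "permil PgC/yr", 3, "standard_error",
                  "stratosphere-to-troposphere anomaly isoflux"),
    .constant_row("m_atmosphere", 828, "PgC", 10, "standard_error",
                  "atmospheric CO2 mass loading"),
    .constant_row("nep", 10, "PgC/yr", NA, "fixed",
                  "net ecosystem productivity"),
    .constant_row("kappa_c_min", 1.33, "-", NA, "range",
                  "stomatal conductance measure, lower bound"),
    .constant_row("kappa_c_max", 2.97, "-", NA, "range",
                  "stomatal conductance measure, upper bound"),
    .constant_row("theta_eq_min", 0.70, "-", NA, "range",
                  "degree of CO2 hydration in stomata, lower bound"),
    .constant_row("theta_eq_max", 0.78, "-", NA, "range",
                  "degree of CO2 hydration in stomata, upper bound"),
    .constant_row("leaf_respiration_factor", 0.88, "-", NA, "fixed",
                  "fraction of gross uptake surviving leaf respiration"),
    .constant_row("eps_leaf", -7.4, "permil", NA, "fixed",
                  "kinetic 18O fractionation, stomatal diffusion"),
    .constant_row("eps_soil", -7.2, "permil", NA, "fixed",
                  "kinetic 18O fractionation, soil efflux"),
    .constant_row("eps_ocean", 0.8, "permil", NA, "fixed",
                  "kinetic 18O fractionation, air-sea exchange")
  )
}

.required_constants <- function() default_constants()$name

#' Flatten a constants table to a named list of values
#'
#' @param constants a constants table as returned by [default_constants()].
#' @return a named list mapping constant name to numeric value.
#' @export
constants_list <- function(constants = default_constants()) {
  validate_constants(constants)
  stats::setNames(as.list(constants$value), constants$name)
}

#' Validate a constants table
#'
#' Checks the schema (columns, error semantics) and that every constant the
#' pipeline consumes is present; a missing constant is reported by name.
#'
#' @inheritParams constants_list
#' @return the table, invisibly, if valid.
#' @export
validate_constants <- function(constants) {
  needed <- c("name", "value", "units", "error", "error_type", "note")
  if (!is.data.frame(constants) || !all(needed %in% names(constants))) {
    stop("constants must be a data.frame with columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(constants$error_type), .error_types)
  if (length(bad)) {
    stop("unknown error_type: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(.required_constants(), constants$name)
  if (length(missing)) {
    stop("missing constant(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(constants$value))) {
    stop("non-finite constant value", call. = FALSE)
  }
  invisible(constants)
}

#' Read / write a constants table
#'
#' The table is serialised as YAML (`.yml`/`.yaml`) or JSON (`.json`),
#' one record per constant; `read_constants()` validates on load so a
#' write-then-read round trip reproduces the table exactly.
#'
#' @param constants a constants table ([default_constants()]).
#' @param path file path; the extension selects the format.
#' @return `read_constants()` returns the validated table;
#'   `write_constants()` returns `path` invisibly.
#' @export
write_constants <- function(constants, path) {
  validate_constants(constants)
  records <- lapply(seq_len(nrow(constants)), function(i) {
    r <- as.list(constants[i, ])
    if (is.na(r$error)) r$error <- NULL
    r
  })
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::write_yaml(records, path)
  } else if (ext == "json") {
    jsonlite::write_json(records, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported config format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_constants
#' @export
read_constants <- function(path) {
  ext <- tolower(tools::file_ext(path))
  records <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path)
  } else {
    stop("unsupported config format: .", ext, call. = FALSE)
  }
  rows <- lapply(records, function(r) {
    err <- r[["error"]] # exact: `error` may be absent, `error_type` not
    .constant_row(r[["name"]], as.numeric(r[["value"]]), r[["units"]],
                  if (is.null(err)) NA_real_ else as.numeric(err),
                  r[["error_type"]],
                  if (is.null(r[["note"]])) "" else r[["note"]])
  })
  validate_constants(do.call(rbind, rows))
}
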