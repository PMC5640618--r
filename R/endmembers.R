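# CO2 source endmembers.
#
# The logarithmic anomalies of the terrestrial and oceanic endmembers are
# always computed from first principles (water anomaly + water-CO2
# equilibration); the anthropogenic value inherits air O2 and is never
# recomputed. For the linear convention two modes exist: "printed" uses the
# established linear constants directly (the d18O values behind the leaf and
# soil values are not independently known), while "computed" converts the
# logarithmic values at documented assumed d18O per pool.

#' Build the CO2 source endmember set
#'
#' Constructs the leaf, respiration, soil, ocean, anthropogenic and land
#' composite endmembers in both anomaly conventions (reference exponent
#' 0.516). Logarithmic values: terrestrial pools from meteoric water
#' (-0.046 permil) equilibrated at 15 C (alpha18 = 1.043), the ocean pool
#' from ocean water (0.000 permil) at 20 C (alpha18 = 1.042), the
#' anthropogenic pool fixed at the air-O2 anomaly (-0.21 permil).
#'
#' @param constants constants table, see [default_constants()].
#' @param mode `"printed"` (default) takes the linear values from the
#'   constants table; `"computed"` derives them from the logarithmic values
#'   at each pool's assumed `d18O` (flagged as reverse-engineered for the
#'   terrestrial and anthropogenic pools).
#' @return a `data.frame` of class `co2_endmembers` with columns `name`,
#'   `cap_log`, `cap_linear`, `d18_assumed` and `provenance`.
#' @examples
#' build_endmembers()
#' @export
build_endmembers <- function(constants = default_constants(),
                             mode = c("printed", "computed")) {
  mode <- match.arg(mode)
  k <- constants_list(constants)

  land <- equilibrate_water_to_co2(k$cap17_meteoric_water, k$alpha18_land,
                                   lambda_ref = k$lambda_0,
                                   lambda_eq = k$lambda_water_co2)
  ocean <- equilibrate_water_to_co2(k$cap17_ocean_water, k$alpha18_ocean,
                                    lambda_ref = k$lambda_0,
                                    lambda_eq = k$lambda_water_co2)

  name <- c("leaf", "respiration", "soil", "ocean", "anthropogenic")
  cap_log <- c(land$cap_log, land$cap_log, land$cap_log,
               ocean$cap_log, k$cap17_anthropogenic)
  d18_assumed <- c(k$d18_leaf_co2, k$d18_soil_co2, k$d18_soil_co2,
                   k$d18_ocean_co2, k$d18_anthropogenic_co2)

  if (mode == "printed") {
    cap_linear <- c(k$delta_leaf, k$delta_respiration, k$delta_soil,
                    k$delta_ocean, k$delta_anthropogenic)
    provenance <- rep("printed-constant", 5L)
  } else {
    cap_linear <- log_to_linear(cap_log, d18_assumed, lambda = k$lambda_0)
    provenance <- rep("computed", 5L)
  }

  out <- data.frame(name = name, cap_log = cap_log, cap_linear = cap_linear,
                    d18_assumed = d18_assumed, provenance = provenance,
                    stringsAsFactors = FALSE)
  class(out) <- c("co2_endmembers", "data.frame")
  out
}

.endmember <- function(set, name, field = "cap_linear") {
  i <- match(name, set$name)
  if (is.na(i)) stop("endmember `", name, "` missing from the set",
                     call. = FALSE)
  set[[field]][i]
}

#' Land composite endmember
#'
#' The terrestrial source enters the steady-state budget as the mean of the
#' leaf and soil/respiration endmembers, reflecting the assumed 2:1:1 split
#' of the terrestrial flux into leaf exchange, respiration and soil
#' invasion.
#'
#' @param set an endmember set from [build_endmembers()].
#' @param form which convention to average, `"linear"` (budget default) or
#'   `"log"`.
#' @return the composite anomaly in permil.
#' @export
land_composite <- function(set, form = c("linear", "log")) {
  form <- match.arg(form)
  field <- if (form == "linear") "cap_linear" else "cap_log"
  (.endmember(set, "leaf", field) + .endmember(set, "soil", field)) / 2
}

#' @export
print.co2_endmembers <- function(x, digits = 4, ...) {
  cat("CO2 source endmembers (anomalies in permil, lambda = 0.516)\n")
  y <- as.data.frame(x)
  y$cap_log <- round(y$cap_log, digits)
  y$cap_linear <- round(y$cap_linear, digits)
  print.data.frame(y, row.names = FALSE, ...)
  invisible(x)
}
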