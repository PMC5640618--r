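# Triple-oxygen-isotope algebra.
#
# All delta and Delta values are carried in permil (vs V-SMOW); they are
# converted to absolute fractions only inside logarithms, so every number in
# and out of these functions matches the conventional reporting scale.

# log-transformed delta in permil: 1000 * ln(1 + delta/1000)
.log_permil <- function(delta) 1000 * log1p(delta / 1000)

# inverse of .log_permil
.exp_permil <- function(l) 1000 * expm1(l / 1000)

.check_delta <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop("`", name, "` must be finite numeric (permil)", call. = FALSE)
  }
  if (any(x <= -1000)) {
    stop("`", name, "` below the physical bound of -1000 permil", call. = FALSE)
  }
  invisible(x)
}

.check_lambda <- function(lambda) {
  if (!is.numeric(lambda) || any(!is.finite(lambda)) ||
      any(lambda < 0.50) || any(lambda > 0.53)) {
    stop("three-isotope exponent `lambda` must lie in [0.50, 0.53]",
         call. = FALSE)
  }
  invisible(lambda)
}

#' Oxygen-17 anomaly, logarithmic convention
#'
#' Computes the triple-oxygen-isotope anomaly
#' \eqn{\Delta'^{17}O = \ln(1+\delta^{17}O) - \lambda \ln(1+\delta^{18}O)}
#' of a pool from its two delta values. This is the convention used for
#' reporting measurements; for flux budgets use the mass-conserving linear
#' form ([cap_delta_linear()]).
#'
#' @param d17,d18 delta-17O and delta-18O in permil vs V-SMOW.
#' @param lambda three-isotope exponent; the package default 0.516 is the
#'   plant-transpiration slope at 75\% relative humidity.
#' @return anomaly in permil (vectorised over the inputs).
#' @examples
#' cap_delta_log(21.107, 40.65)          # tropospheric CO2-like pair
#' cap_delta_log(0, 0)                   # identity at the reference
#' @seealso [cap_delta_linear()], [log_to_linear()], [rescale_lambda()]
#' @export
cap_delta_log <- function(d17, d18, lambda = 0.516) {
  .check_delta(d17, "d17")
  .check_delta(d18, "d18")
  .check_lambda(lambda)
  .log_permil(d17) - lambda * .log_permil(d18)
}

#' Oxygen-17 anomaly, linear convention
#'
#' The linear anomaly \eqn{\Delta = \delta^{17}O - \lambda\,\delta^{18}O}.
#' Unlike the logarithmic form, this quantity is conserved under
#' multi-component mixing and is therefore the working variable of the
#' steady-state budget ([solve_budget()]).
#'
#' @inheritParams cap_delta_log
#' @return anomaly in permil.
#' @export
cap_delta_linear <- function(d17, d18, lambda = 0.516) {
  .check_delta(d17, "d17")
  .check_delta(d18, "d18")
  .check_lambda(lambda)
  d17 - lambda * d18
}

#' Recover delta-17O from a logarithmic anomaly
#'
#' Inverts [cap_delta_log()] at known delta-18O.
#'
#' @param cap_log anomaly in permil, logarithmic convention.
#' @param d18 delta-18O of the same pool, permil.
#' @inheritParams cap_delta_log
#' @return delta-17O in permil.
#' @export
d17_from_cap_log <- function(cap_log, d18, lambda = 0.516) {
  .check_delta(d18, "d18")
  .check_lambda(lambda)
  if (!is.numeric(cap_log) || any(!is.finite(cap_log))) {
    stop("`cap_log` must be finite numeric", call. = FALSE)
  }
  .exp_permil(cap_log + lambda * .log_permil(d18))
}

#' Convert an anomaly between logarithmic and linear conventions
#'
#' The two conventions agree at delta = 0 and diverge slowly with delta-18O;
#' converting requires the delta-18O of the pool the anomaly describes.
#' `log_to_linear()` and `linear_to_log()` are exact inverses.
#'
#' @param cap_log,cap_linear anomaly in permil in the source convention.
#' @param d18 delta-18O of the pool, permil.
#' @inheritParams cap_delta_log
#' @return anomaly in permil in the target convention.
#' @examples
#' log_to_linear(0.326, d18 = 41)   # tropospheric anomaly on the budget scale
#' @export
log_to_linear <- function(cap_log, d18, lambda = 0.516) {
  if (missing(d18)) stop("`d18` of the pool is required", call. = FALSE)
  d17 <- d17_from_cap_log(cap_log, d18, lambda)
  d17 - lambda * d18
}

#' @rdname log_to_linear
#' @export
linear_to_log <- function(cap_linear, d18, lambda = 0.516) {
  if (missing(d18)) stop("`d18` of the pool is required", call. = FALSE)
  .check_delta(d18, "d18")
  .check_lambda(lambda)
  d17 <- cap_linear + lambda * d18
  .check_delta(d17, "implied d17")
  .log_permil(d17) - lambda * .log_permil(d18)
}

#' Re-express a logarithmic anomaly under a different reference exponent
#'
#' Exact algebraic rescaling between two lambda conventions:
#' \eqn{\Delta'^{17}O(\lambda_2) = \Delta'^{17}O(\lambda_1) +
#' (\lambda_1-\lambda_2)\ln(1+\delta^{18}O)}. Used e.g. to move
#' meteoric-water anomalies from the 0.528 meteoric-water-line convention to
#' the 0.516 reference used throughout this package.
#'
#' @param cap_log anomaly in permil under `lambda_from`.
#' @param d18 delta-18O of the pool, permil (required).
#' @param lambda_from,lambda_to source and target exponents.
#' @return anomaly in permil under `lambda_to`.
#' @examples
#' rescale_lambda(0.032, d18 = -6.5, lambda_from = 0.528, lambda_to = 0.516)
#' @export
rescale_lambda <- function(cap_log, d18, lambda_from, lambda_to) {
  if (missing(d18)) stop("`d18` of the pool is required", call. = FALSE)
  .check_delta(d18, "d18")
  .check_lambda(lambda_from)
  .check_lambda(lambda_to)
  cap_log + (lambda_from - lambda_to) * .log_permil(d18)
}

#' Anomaly of CO2 equilibrated with a water pool
#'
#' Isotope exchange between CO2 and water follows the water-CO2 equilibrium
#' exponent 0.5229, so CO2 equilibrated with a water of anomaly
#' \eqn{\Delta'^{17}O_w} acquires, in a reference convention `lambda_ref`,
#' \deqn{\Delta'^{17}O_{CO2} = (0.5229 - \lambda_{ref})\,\ln\alpha^{18} +
#'   \Delta'^{17}O_w,}
#' where \eqn{\alpha^{18}} is the 18-O water-CO2 equilibrium fractionation
#' factor (1.043 at 15 C over land, 1.042 at 20 C for the surface ocean).
#'
#' @param cap_water anomaly of the water pool, permil (logarithmic, in
#'   `lambda_ref`).
#' @param alpha18 18-O equilibrium fractionation factor, must be > 0.
#' @param lambda_ref reference exponent of the result (default 0.516).
#' @param lambda_eq water-CO2 equilibrium exponent (default 0.5229).
#' @param d18_water optional delta-18O of the water; when given, the
#'   delta-18O of the equilibrated CO2 is returned as well.
#' @return a list with `cap_log` (permil) and, when `d18_water` is supplied,
#'   `d18_co2` (permil).
#' @examples
#' equilibrate_water_to_co2(-0.046, 1.043)  # terrestrial leaf/soil CO2
#' equilibrate_water_to_co2( 0.000, 1.042)  # surface-ocean CO2
#' @export
equilibrate_water_to_co2 <- function(cap_water, alpha18, lambda_ref = 0.516,
                                     lambda_eq = 0.5229, d18_water = NULL) {
  if (!is.numeric(alpha18) || any(!is.finite(alpha18)) || any(alpha18 <= 0)) {
    stop("`alpha18` must be a positive fractionation factor", call. = FALSE)
  }
  .check_lambda(lambda_ref)
  .check_lambda(lambda_eq)
  out <- list(cap_log = (lambda_eq - lambda_ref) * 1000 * log(alpha18) +
                cap_water)
  if (!is.null(d18_water)) {
    .check_delta(d18_water, "d18_water")
    out$d18_co2 <- 1000 * (alpha18 * (1 + d18_water / 1000) - 1)
  }
  out
}

#' Transpiration sensitivity of the terrestrial water anomaly
#'
#' At 75\% relative humidity the transpiration exponent equals the package
#' reference (0.516), so transpiration leaves the anomaly of leaf water
#' unchanged. Away from 75\% RH the anomaly of leaf-water-equilibrated CO2
#' shifts by about 0.015 permil per 0.05 RH; this linearised shift is used
#' as an uncertainty term, with sign equal to `sign(rh - 0.75)`.
#'
#' @param rh relative humidity as a fraction in (0, 1].
#' @param sensitivity shift magnitude (permil) per `per` RH deviation; the
#'   source-process sensitivity is 0.015, the error-budget value 0.017.
#' @param per RH deviation over which `sensitivity` applies (default 0.05).
#' @return signed anomaly shift in permil (0 at rh = 0.75).
#' @export
transpiration_shift <- function(rh, sensitivity = 0.015, per = 0.05) {
  if (!is.numeric(rh) || any(!is.finite(rh)) || any(rh <= 0) || any(rh > 1)) {
    stop("`rh` must be a fraction in (0, 1]", call. = FALSE)
  }
  sensitivity * (rh - 0.75) / per
}
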