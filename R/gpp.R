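# GPP and soil-invasion inversion.
#
# The gross terrestrial flux partitions into leaf exchange and
# soil/respiration pathways. With theta_eq the degree of CO2 hydration in
# stomata and kappa_c the stomatal-conductance measure, net leaf uptake is
#
#   0.88 * GPP = F_al - F_la = (F_land - F_s) / (theta_eq * kappa_c + 1)
#
# and, closing with GPP = NEP + F_r = NEP + F_s (soil invasion as large as
# respiration), GPP has the closed form
#
#   GPP = (F_land + NEP) / (0.88 * (theta_eq * kappa_c + 1) + 1).

#' Stomatal-conductance measure from the chloroplast/ambient CO2 ratio
#'
#' \eqn{\kappa_c = r / (1 - r)} with \eqn{r = C_c / C_a}, the ratio of the
#' chloroplast CO2 concentration (at the site of hydration) to the ambient
#' concentration. Typical values: r = 2/3 for C3 plants, 1/3 for C4, and a
#' global average near 0.57 (kappa_c = 1.33).
#'
#' @param cc_over_ca ratio in (0, 1).
#' @return kappa_c (dimensionless).
#' @examples
#' kappa_from_cc_ratio(0.57)
#' @export
kappa_from_cc_ratio <- function(cc_over_ca) {
  if (any(!is.finite(cc_over_ca)) || any(cc_over_ca <= 0) ||
      any(cc_over_ca >= 1)) {
    stop("`cc_over_ca` must lie strictly in (0, 1)", call. = FALSE)
  }
  cc_over_ca / (1 - cc_over_ca)
}

#' Plant-uptake scenario
#'
#' @param kappa_c stomatal-conductance measure (literature range
#'   1.33-2.97).
#' @param theta_eq degree of CO2 hydration in stomata, set by carbonic
#'   anhydrase activity (range 0.70-0.78).
#' @param nep net ecosystem productivity, PgC/yr.
#' @param leaf_respiration_factor fraction of gross uptake surviving leaf
#'   respiration (default 0.88).
#' @return a list of class `uptake_scenario`.
#' @export
uptake_scenario <- function(kappa_c = 1.33, theta_eq = 0.78, nep = 10,
                            leaf_respiration_factor = 0.88) {
  stopifnot(is.finite(kappa_c), kappa_c > 0,
            is.finite(theta_eq), theta_eq > 0,
            is.finite(nep))
  if (leaf_respiration_factor <= 0 || leaf_respiration_factor > 1) {
    stop("`leaf_respiration_factor` must be in (0, 1]", call. = FALSE)
  }
  structure(list(kappa_c = kappa_c, theta_eq = theta_eq, nep = nep,
                 leaf_respiration_factor = leaf_respiration_factor),
            class = "uptake_scenario")
}

#' Invert the terrestrial flux for GPP and soil invasion
#'
#' Solves the leaf-uptake relation together with the closure
#' `GPP = NEP + F_s` (soil invasion equal to respiration) for gross primary
#' productivity and the soil-invasion flux. The returned pair satisfies
#' both relations simultaneously to machine precision.
#'
#' @param f_land terrestrial cycling flux, PgC/yr (must exceed `nep`).
#' @param scenario an [uptake_scenario()].
#' @return a list of class `gpp_result` with `gpp`, `f_s` and `f_r`
#'   (PgC/yr). When `f_land` is so close to `nep` that the closure would
#'   imply negative soil invasion, the result is clamped to the physical
#'   edge (`gpp = nep`, `f_s = 0`) and flagged `degenerate`.
#' @examples
#' solve_gpp(345, uptake_scenario(kappa_c = 1.33, theta_eq = 0.78))
#' @export
solve_gpp <- function(f_land, scenario = uptake_scenario()) {
  stopifnot(inherits(scenario, "uptake_scenario"), is.finite(f_land))
  if (f_land < scenario$nep) {
    stop("`f_land` (", signif(f_land, 4),
         ") must be at least NEP (", scenario$nep, ")", call. = FALSE)
  }
  b <- scenario$leaf_respiration_factor
  denom <- b * (scenario$theta_eq * scenario$kappa_c + 1) + 1
  gpp <- (f_land + scenario$nep) / denom
  degenerate <- gpp < scenario$nep
  if (degenerate) {
    # closure implies negative soil invasion; clamp to the physical edge
    gpp <- scenario$nep
  }
  structure(list(gpp = gpp, f_s = gpp - scenario$nep,
                 f_r = gpp - scenario$nep, f_land = f_land,
                 degenerate = degenerate, scenario = scenario),
            class = "gpp_result")
}

#' @export
print.gpp_result <- function(x, ...) {
  s <- x$scenario
  cat("GPP inversion (kappa_c =", s$kappa_c, ", theta_eq =", s$theta_eq,
      ", NEP =", s$nep, "PgC/yr)\n")
  cat(sprintf("  GPP           : %6.1f PgC/yr (%s at 2 s.f.)\n", x$gpp,
              format(signif(x$gpp, 2))))
  cat(sprintf("  soil invasion : %6.1f PgC/yr (%s at 2 s.f.)\n", x$f_s,
              format(signif(x$f_s, 2))))
  invisible(x)
}

#' GPP at a prescribed soil-invasion flux
#'
#' Decoupled form of the inversion used for soil-invasion sensitivity
#' scans: `gpp = (f_land - f_s) / (0.88 * (theta_eq * kappa_c + 1))`,
#' without the `GPP = NEP + F_s` closure.
#'
#' @param f_land terrestrial cycling flux, PgC/yr.
#' @param f_s soil-invasion flux, PgC/yr, in `[0, f_land]`.
#' @param scenario an [uptake_scenario()].
#' @return GPP in PgC/yr (vectorised over `f_s`).
#' @export
gpp_given_fs <- function(f_land, f_s, scenario = uptake_scenario()) {
  stopifnot(inherits(scenario, "uptake_scenario"))
  if (any(f_s < 0) || any(f_s > f_land)) {
    stop("`f_s` must lie in [0, f_land]", call. = FALSE)
  }
  b <- scenario$leaf_respiration_factor
  (f_land - f_s) / (b * (scenario$theta_eq * scenario$kappa_c + 1))
}
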