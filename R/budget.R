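# Steady-state isoflux budget of tropospheric CO2.
#
# At steady state the anomaly-weighted fluxes (isofluxes, permil PgC/yr)
# into and out of the troposphere balance:
#
#   F_land (Dl - Da + Ds - Da)/2 + F_ao (Do - Da)
#     + F_anth (Danth - Da) + F_st (Dst - Da) = 0
#
# with all anomalies in the LINEAR convention, which is conserved under
# mixing. Solving for F_land gives the gross terrestrial cycling flux; the
# oxygen-isotope residence time is tau = M / (F_land + F_ao).

#' Assemble the inputs of the steady-state budget
#'
#' @param cap_a_log tropospheric CO2 anomaly, permil, logarithmic
#'   convention (four-site observational mean by default).
#' @param d18_a delta-18O of tropospheric CO2 (permil) used to convert the
#'   anomaly to the linear convention.
#' @param f_ao gross air-to-ocean CO2 flux, PgC/yr.
#' @param f_anth anthropogenic CO2 flux, PgC/yr.
#' @param strat_isoflux stratosphere-to-troposphere anomaly isoflux,
#'   permil PgC/yr (the product of the cross-tropopause flux and its
#'   anomaly contrast; only the product is constrained).
#' @param m atmospheric CO2 mass loading, PgC.
#' @param endmembers endmember set from [build_endmembers()].
#' @param flux_split relative split of the terrestrial flux into leaf
#'   exchange, respiration and soil invasion (default 2:1:1).
#' @return a list of class `budget_inputs`.
#' @export
budget_inputs <- function(cap_a_log = 0.326, d18_a = 41.0, f_ao = 90,
                          f_anth = 9.4, strat_isoflux = 50, m = 828,
                          endmembers = build_endmembers(),
                          flux_split = c(leaf = 2, respiration = 1,
                                         soil = 1)) {
  stopifnot(is.finite(cap_a_log), is.finite(d18_a))
  if (f_ao < 0 || f_anth < 0 || strat_isoflux < 0 || m <= 0) {
    stop("fluxes and the stratospheric isoflux must be >= 0 and `m` > 0",
         call. = FALSE)
  }
  if (length(flux_split) != 3L || any(flux_split <= 0)) {
    stop("`flux_split` must be three positive weights", call. = FALSE)
  }
  structure(list(cap_a_log = cap_a_log, d18_a = d18_a, f_ao = f_ao,
                 f_anth = f_anth, strat_isoflux = strat_isoflux, m = m,
                 endmembers = endmembers, flux_split = flux_split),
            class = "budget_inputs")
}

#' Construct budget inputs from a constants table
#'
#' @param constants constants table, see [default_constants()].
#' @param mode endmember mode passed to [build_endmembers()].
#' @return a `budget_inputs` object.
#' @export
budget_inputs_from_constants <- function(constants = default_constants(),
                                         mode = "printed") {
  k <- constants_list(constants)
  budget_inputs(cap_a_log = k$cap17_atmosphere, d18_a = k$d18_atmosphere,
                f_ao = k$f_ao, f_anth = k$f_anth,
                strat_isoflux = k$strat_isoflux, m = k$m_atmosphere,
                endmembers = build_endmembers(constants, mode))
}

# closed-form F_land from linear anomalies; vectorised over cap_a_lin
.f_land_closed <- function(cap_a_lin, land, ocean, anth, f_ao, f_anth,
                           strat_isoflux) {
  num <- strat_isoflux + f_ao * (ocean - cap_a_lin) +
    f_anth * (anth - cap_a_lin)
  num / (cap_a_lin - land)
}

#' Solve the steady-state budget for the terrestrial flux
#'
#' Converts the tropospheric anomaly to the linear convention, solves the
#' isoflux balance for the gross terrestrial cycling flux `f_land`, splits
#' it into leaf exchange, respiration and soil invasion (2:1:1 by default),
#' and derives the oxygen-isotope residence time `tau = m / f_sur` with
#' `f_sur = f_land + f_ao`.
#'
#' The budget must be solved in the linear convention; `convention =
#' "logarithmic"` is a clearly non-default diagnostic that substitutes the
#' logarithmic anomalies to quantify the convention bias and attaches a
#' `diagnostic` flag to the result.
#'
#' @param inputs a [budget_inputs()] object.
#' @param convention `"linear"` (the mass-conserving default) or
#'   `"logarithmic"` (diagnostic only).
#' @return a list of class `budget_solution` with elements `f_land`,
#'   `f_sur`, `tau`, `f_la`, `f_r`, `f_s`, `cap_a_linear`, `isofluxes`
#'   (named, permil PgC/yr, summing to zero) and `convention`.
#' @examples
#' solve_budget(budget_inputs())
#' @export
solve_budget <- function(inputs, convention = c("linear", "logarithmic")) {
  convention <- match.arg(convention)
  stopifnot(inherits(inputs, "budget_inputs"))
  em <- inputs$endmembers
  if (convention == "linear") {
    cap_a <- log_to_linear(inputs$cap_a_log, inputs$d18_a)
    land <- land_composite(em, "linear")
    ocean <- .endmember(em, "ocean", "cap_linear")
    anth <- .endmember(em, "anthropogenic", "cap_linear")
  } else {
    cap_a <- inputs$cap_a_log
    land <- land_composite(em, "log")
    ocean <- .endmember(em, "ocean", "cap_log")
    anth <- .endmember(em, "anthropogenic", "cap_log")
  }
  if (cap_a <= land) {
    stop("degenerate budget: atmospheric anomaly (", signif(cap_a, 4),
         " permil linear) does not exceed the land composite (",
         signif(land, 4), " permil)", call. = FALSE)
  }
  f_land <- .f_land_closed(cap_a, land, ocean, anth, inputs$f_ao,
                           inputs$f_anth, inputs$strat_isoflux)
  if (f_land < 0) {
    if (f_land > -1e-9) {
      f_land <- 0 # exact isoflux cancellation up to round-off
    } else {
      stop("non-physical budget: solved terrestrial flux is negative (",
           signif(f_land, 4), " PgC/yr); inputs are inconsistent",
           call. = FALSE)
    }
  }
  split <- inputs$flux_split / sum(inputs$flux_split)
  f_sur <- f_land + inputs$f_ao
  isofluxes <- c(terrestrial = f_land * (land - cap_a),
                 oceanic = inputs$f_ao * (ocean - cap_a),
                 anthropogenic = inputs$f_anth * (anth - cap_a),
                 stratospheric = inputs$strat_isoflux)
  structure(list(f_land = f_land, f_sur = f_sur, tau = inputs$m / f_sur,
                 f_la = f_land * split[[1]], f_r = f_land * split[[2]],
                 f_s = f_land * split[[3]], cap_a_linear = cap_a,
                 isofluxes = isofluxes, convention = convention,
                 diagnostic = convention != "linear", inputs = inputs),
            class = "budget_solution")
}

#' @export
print.budget_solution <- function(x, ...) {
  cat("Steady-state CO2 triple-oxygen budget (", x$convention,
      " convention", if (x$diagnostic) ", DIAGNOSTIC" else "", ")\n",
      sep = "")
  cat(sprintf("  terrestrial flux F_land : %6.1f PgC/yr\n", x$f_land))
  cat(sprintf("  surface flux F_sur      : %6.1f PgC/yr\n", x$f_sur))
  cat(sprintf("  residence time tau      : %6.2f yr\n", x$tau))
  cat(sprintf("  atmospheric anomaly     : %6.4f permil (linear)\n",
              x$cap_a_linear))
  cat("  isofluxes (permil PgC/yr):\n")
  for (n in names(x$isofluxes)) {
    cat(sprintf("    %-14s %8.2f\n", n, x$isofluxes[[n]]))
  }
  invisible(x)
}

#' Per-source isoflux decomposition
#'
#' @param sol a [solve_budget()] solution.
#' @return a `data.frame` with one row per source (plus the total, which is
#'   zero at the solution), in permil PgC/yr.
#' @export
isoflux_table <- function(sol) {
  stopifnot(inherits(sol, "budget_solution"))
  data.frame(source = c(names(sol$isofluxes), "total"),
             isoflux = c(unname(sol$isofluxes), sum(sol$isofluxes)),
             stringsAsFactors = FALSE)
}

#' Budget solutions over a grid of atmospheric anomalies
#'
#' Re-solves the budget row-wise over `cap_a_grid` (logarithmic permil).
#' Grid values that make the budget degenerate or non-physical are flagged
#' in the `flag` column rather than dropped.
#'
#' @param inputs a [budget_inputs()] object.
#' @param cap_a_grid numeric vector of tropospheric anomalies, permil.
#' @return a `data.frame` with columns `cap_a_log`, `f_land`, `f_ocean`,
#'   `tau`, the four isofluxes and `flag`.
#' @export
budget_curves <- function(inputs, cap_a_grid) {
  stopifnot(inherits(inputs, "budget_inputs"), length(cap_a_grid) >= 1)
  rows <- lapply(cap_a_grid, function(ca) {
    ins <- inputs
    ins$cap_a_log <- ca
    sol <- tryCatch(solve_budget(ins), error = function(e) e)
    if (inherits(sol, "error")) {
      data.frame(cap_a_log = ca, f_land = NA_real_, f_ocean = inputs$f_ao,
                 tau = NA_real_, terrestrial = NA_real_, oceanic = NA_real_,
                 anthropogenic = NA_real_,
                 stratospheric = inputs$strat_isoflux,
                 flag = conditionMessage(sol), stringsAsFactors = FALSE)
    } else {
      data.frame(cap_a_log = ca, f_land = sol$f_land, f_ocean = inputs$f_ao,
                 tau = sol$tau, terrestrial = sol$isofluxes[["terrestrial"]],
                 oceanic = sol$isofluxes[["oceanic"]],
                 anthropogenic = sol$isofluxes[["anthropogenic"]],
                 stratospheric = sol$isofluxes[["stratospheric"]],
                 flag = "ok", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Bound on the neglected kinetic isoflux terms
#'
#' The steady-state budget drops the kinetic-fractionation terms
#' `F * eps * (lambda - lambda_0)` for the leaf (net flux), soil-respiration
#' and air-sea pathways. This reports each term and the total so the
#' negligibility claim (< 1 permil PgC/yr under extreme exponents) can be
#' checked for any flux assumptions. The leaf flux is the NET leaf exchange
#' `F_la - F_al`, not the gross flux.
#'
#' @param net_flux named numeric: net fluxes (PgC/yr) for `leaf`, `soil`
#'   and `ocean` pathways.
#' @param eps kinetic 18-O fractionations, permil (defaults -7.4, -7.2,
#'   0.8).
#' @param lambda pathway three-isotope exponents in `[0.5, 0.53]`; default
#'   0.529, the extreme value for liquid-vapour equilibrium.
#' @param lambda_0 reference exponent.
#' @return a list with `terms` (a `data.frame`) and `total`
#'   (permil PgC/yr).
#' @examples
#' kinetic_bound(c(leaf = 10, soil = 86, ocean = 90))
#' @export
kinetic_bound <- function(net_flux,
                          eps = c(leaf = -7.4, soil = -7.2, ocean = 0.8),
                          lambda = c(leaf = 0.529, soil = 0.529,
                                     ocean = 0.529),
                          lambda_0 = 0.516) {
  pathways <- c("leaf", "soil", "ocean")
  if (!all(pathways %in% names(net_flux))) {
    stop("`net_flux` must name leaf, soil and ocean pathways",
         call. = FALSE)
  }
  .check_lambda(lambda)
  .check_lambda(lambda_0)
  terms <- vapply(pathways, function(p) {
    net_flux[[p]] * eps[[p]] * (lambda[[p]] - lambda_0)
  }, numeric(1))
  list(terms = data.frame(pathway = pathways,
                          net_flux = unname(net_flux[pathways]),
                          eps = unname(eps[pathways]),
                          lambda = unname(lambda[pathways]),
                          term = unname(terms),
                          stringsAsFactors = FALSE),
       total = sum(terms))
}

#' Atmospheric anomaly implied by a terrestrial flux
#'
#' Inverts the steady-state budget: given a terrestrial flux, returns the
#' tropospheric anomaly (logarithmic, at `inputs$d18_a`) that balances the
#' isofluxes. Used for forward simulation and parameter-recovery checks;
#' `solve_budget()` composed with this function is the identity.
#'
#' @param f_land terrestrial flux, PgC/yr.
#' @param inputs a [budget_inputs()] object.
#' @return tropospheric anomaly in permil, logarithmic convention.
#' @export
cap_a_from_f_land <- function(f_land, inputs) {
  stopifnot(inherits(inputs, "budget_inputs"), all(f_land >= 0))
  em <- inputs$endmembers
  land <- land_composite(em, "linear")
  ocean <- .endmember(em, "ocean", "cap_linear")
  anth <- .endmember(em, "anthropogenic", "cap_linear")
  cap_a_lin <- (inputs$strat_isoflux + inputs$f_ao * ocean +
                  inputs$f_anth * anth + f_land * land) /
    (f_land + inputs$f_ao + inputs$f_anth)
  linear_to_log(cap_a_lin, inputs$d18_a)
}
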