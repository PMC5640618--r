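# Uncertainty propagation: analytic first-order (root-sum-square of
# derivative-weighted input errors) and seeded Monte Carlo over measurement
# error and plant-uptake scenario ranges.

#' First-order standard-error propagation
#'
#' Numerically propagates independent input uncertainties through a scalar
#' function: \eqn{\sigma_f^2 = \sum_i (\partial f/\partial x_i)^2
#' \sigma_i^2}, with derivatives by central differences (step `rel_step`
#' times the input scale). Works identically for standard errors of sample
#' means and for single-measurement standard deviations; the semantics of
#' the result follow the semantics of the inputs.
#'
#' @param f function of one named numeric vector, returning a scalar.
#' @param x named numeric vector of central input values.
#' @param se uncertainties of `x` (same length/order), all >= 0.
#' @param rel_step relative finite-difference step (default 1e-6).
#' @return a list with `value`, `se`, and `contributions` (a `data.frame`
#'   with per-input derivative, input error, output contribution and
#'   fractional variance share).
#' @examples
#' propagate_se(function(x) x[["a"]] + x[["b"]], c(a = 1, b = 1),
#'              se = c(3, 4))  # 3-4-5
#' @export
propagate_se <- function(f, x, se, rel_step = 1e-6) {
  stopifnot(is.numeric(x), is.numeric(se), length(se) == length(x))
  if (any(se < 0)) stop("uncertainties must be >= 0", call. = FALSE)
  value <- f(x)
  if (!is.finite(value)) stop("f(x) is not finite at the central values",
                              call. = FALSE)
  grad <- vapply(seq_along(x), function(i) {
    h <- rel_step * max(abs(x[[i]]), 1)
    xp <- x; xp[[i]] <- x[[i]] + h
    xm <- x; xm[[i]] <- x[[i]] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
  if (any(!is.finite(grad))) {
    stop("degenerate derivative: f is not differentiable at `x`",
         call. = FALSE)
  }
  var_i <- (grad * se)^2
  total <- sum(var_i)
  share <- if (total > 0) var_i / total else rep(0, length(var_i))
  list(value = value, se = sqrt(total),
       contributions = data.frame(term = names(x), derivative = grad,
                                  se_in = se, se_out = abs(grad * se),
                                  share = share, stringsAsFactors = FALSE))
}

#' Error model of the steady-state budget
#'
#' One row per uncertain budget input with both error semantics: `se` is
#' the standard error of the sample mean (the default propagation), `sd`
#' the single-measurement standard deviation. Only the tropospheric anomaly
#' has an independently known single-measurement spread (0.039 permil);
#' for the other terms `sd` falls back to `se`, so the single-measurement
#' case is a lower bound. `land_shift` is a common additive shift of the
#' leaf and soil linear endmembers (their quoted error), and `trans_shift`
#' the transpiration relative-humidity term (0.017 permil), also applied
#' to both terrestrial endmembers.
#'
#' @param constants constants table, see [default_constants()].
#' @return a `data.frame` with columns `term`, `se` and `sd`.
#' @export
budget_error_model <- function(constants = default_constants()) {
  k <- constants_list(constants)
  err <- function(name) constants$error[match(name, constants$name)]
  data.frame(
    term = c("cap_a_log", "land_shift", "trans_shift", "cap_ocean",
             "cap_anth", "f_ao", "f_anth", "strat_isoflux"),
    se = c(err("cap17_atmosphere"), err("delta_leaf"),
           k$rh_sensitivity_error, err("delta_ocean"),
           err("delta_anthropogenic"), err("f_ao"), err("f_anth"),
           err("strat_isoflux")),
    sd = c(k$cap17_atmosphere_sd, err("delta_leaf"),
           k$rh_sensitivity_error, err("delta_ocean"),
           err("delta_anthropogenic"), err("f_ao"), err("f_anth"),
           err("strat_isoflux")),
    stringsAsFactors = FALSE)
}

# parameterise the budget for propagation: x holds the uncertain inputs,
# shifts enter the terrestrial endmembers additively (linear convention)
.budget_error_fn <- function(inputs, output = c("f_land", "tau")) {
  output <- match.arg(output)
  em <- inputs$endmembers
  land0 <- land_composite(em, "linear")
  function(x) {
    cap_a <- log_to_linear(x[["cap_a_log"]], inputs$d18_a)
    land <- land0 + x[["land_shift"]] + x[["trans_shift"]]
    f_land <- .f_land_closed(cap_a, land, x[["cap_ocean"]], x[["cap_anth"]],
                             x[["f_ao"]], x[["f_anth"]],
                             x[["strat_isoflux"]])
    if (output == "f_land") f_land else inputs$m / (f_land + x[["f_ao"]])
  }
}

.budget_error_x <- function(inputs) {
  em <- inputs$endmembers
  c(cap_a_log = inputs$cap_a_log, land_shift = 0, trans_shift = 0,
    cap_ocean = .endmember(em, "ocean", "cap_linear"),
    cap_anth = .endmember(em, "anthropogenic", "cap_linear"),
    f_ao = inputs$f_ao, f_anth = inputs$f_anth,
    strat_isoflux = inputs$strat_isoflux)
}

#' Analytic standard error of the solved budget
#'
#' Propagates the error model through the budget solution for the
#' terrestrial flux (or the residence time). The contribution table
#' reports each input's fractional share of the output variance, so the
#' dominance of the transpiration and stratospheric terms is directly
#' checkable.
#'
#' @param inputs a [budget_inputs()] object.
#' @param error_model from [budget_error_model()].
#' @param output propagate to `"f_land"` (default) or `"tau"`.
#' @param semantics use the `"standard_error"` column (sample means,
#'   default) or `"standard_deviation"` (single measurement).
#' @return as [propagate_se()].
#' @export
budget_standard_error <- function(inputs = budget_inputs(),
                                  error_model = budget_error_model(),
                                  output = "f_land",
                                  semantics = c("standard_error",
                                                "standard_deviation")) {
  semantics <- match.arg(semantics)
  x <- .budget_error_x(inputs)
  col <- if (semantics == "standard_error") "se" else "sd"
  errs <- stats::setNames(error_model[[col]], error_model$term)[names(x)]
  if (any(is.na(errs))) {
    stop("error model must cover: ", paste(names(x), collapse = ", "),
         call. = FALSE)
  }
  propagate_se(.budget_error_fn(inputs, output), x, unname(errs))
}

#' Single-measurement error of the solved budget
#'
#' Same propagation machinery as [budget_standard_error()] but with
#' single-measurement standard deviations, quantifying the spread expected
#' if each budget input were measured once (spatiotemporal source
#' inhomogeneity rather than the error of the mean).
#'
#' @inheritParams budget_standard_error
#' @return as [propagate_se()].
#' @export
single_measurement_error <- function(inputs = budget_inputs(),
                                     error_model = budget_error_model(),
                                     output = "f_land") {
  budget_standard_error(inputs, error_model, output,
                        semantics = "standard_deviation")
}

#' Monte Carlo uncertainty for GPP and soil invasion
#'
#' Draws plant-uptake scenarios (`kappa_c`, `theta_eq` uniform over their
#' literature ranges) and terrestrial-flux realisations, inverts each draw
#' for GPP and soil invasion, and summarises the posterior. Three sampling
#' modes:
#' \describe{
#'   \item{joint}{independent joint draws with
#'     `f_land ~ Normal(f_land["mean"], f_land["se"])` (default; 125,000
#'     draws are statistically equivalent to a full factorial for means and
#'     standard deviations).}
#'   \item{factorial}{full factorial over `n_per_var` random draws of each
#'     of the three variables (`n_per_var^3` evaluations).}
#'   \item{coupled}{re-solves the steady-state budget per draw from normal
#'     draws of the tropospheric anomaly, endmember shifts, fluxes and
#'     stratospheric isoflux (per the error model), instead of drawing
#'     `f_land` directly.}
#' }
#' Draws with a non-positive or degenerate terrestrial flux (below NEP)
#' are rejected and counted. Results are bit-for-bit reproducible at a
#' fixed seed.
#'
#' @param seed integer RNG seed (sets the R RNG).
#' @param n_draws number of joint/coupled draws.
#' @param mode sampling layout, see above.
#' @param f_land named vector `c(mean =, se =)` for the terrestrial flux
#'   (joint/factorial modes).
#' @param kappa_range,theta_range uniform bounds for the scenario draws.
#' @param nep net ecosystem productivity, PgC/yr.
#' @param inputs a [budget_inputs()] object (coupled mode).
#' @param error_model from [budget_error_model()] (coupled mode).
#' @param n_per_var per-variable draws in factorial mode.
#' @param keep_draws retain the draw-level table in the result.
#' @return a list of class `mc_result`: `summary` (mean, sd and quantiles
#'   per output), `n_draws`, `n_used`, `n_rejected`, `rejection_fraction`,
#'   `convergence` (full-sample vs half-sample means against 2 MC standard
#'   errors), `seed`, `mode`, and optionally `draws`.
#' @examples
#' run_monte_carlo(seed = 1, n_draws = 2000)
#' @export
run_monte_carlo <- function(seed, n_draws = 125000L,
                            mode = c("joint", "factorial", "coupled"),
                            f_land = c(mean = 345, se = 70),
                            kappa_range = c(1.33, 2.97),
                            theta_range = c(0.70, 0.78), nep = 10,
                            inputs = budget_inputs(),
                            error_model = budget_error_model(),
                            n_per_var = 50L, keep_draws = FALSE) {
  mode <- match.arg(mode)
  stopifnot(length(seed) == 1L, is.finite(seed), n_draws >= 1)
  set.seed(as.integer(seed))

  if (mode == "joint") {
    n <- as.integer(n_draws)
    f <- stats::rnorm(n, f_land[["mean"]], f_land[["se"]])
    kappa <- stats::runif(n, kappa_range[1], kappa_range[2])
    theta <- stats::runif(n, theta_range[1], theta_range[2])
  } else if (mode == "factorial") {
    stopifnot(n_per_var >= 1)
    fv <- stats::rnorm(n_per_var, f_land[["mean"]], f_land[["se"]])
    kv <- stats::runif(n_per_var, kappa_range[1], kappa_range[2])
    tv <- stats::runif(n_per_var, theta_range[1], theta_range[2])
    g <- expand.grid(f = fv, kappa = kv, theta = tv,
                     KEEP.OUT.ATTRS = FALSE)
    f <- g$f; kappa <- g$kappa; theta <- g$theta
    n <- length(f)
  } else { # coupled: re-solve the budget per draw
    n <- as.integer(n_draws)
    em_tab <- error_model
    s <- function(term) em_tab$se[match(term, em_tab$term)]
    x0 <- .budget_error_x(inputs)
    cap_a_log <- stats::rnorm(n, x0[["cap_a_log"]], s("cap_a_log"))
    land <- land_composite(inputs$endmembers, "linear") +
      stats::rnorm(n, 0, s("land_shift")) +
      stats::rnorm(n, 0, s("trans_shift"))
    cap_o <- stats::rnorm(n, x0[["cap_ocean"]], s("cap_ocean"))
    cap_an <- stats::rnorm(n, x0[["cap_anth"]], s("cap_anth"))
    f_ao <- stats::rnorm(n, x0[["f_ao"]], s("f_ao"))
    f_anth <- stats::rnorm(n, x0[["f_anth"]], s("f_anth"))
    strat <- stats::rnorm(n, x0[["strat_isoflux"]], s("strat_isoflux"))
    cap_a <- log_to_linear(cap_a_log, inputs$d18_a)
    f <- .f_land_closed(cap_a, land, cap_o, cap_an, f_ao, f_anth, strat)
    f[cap_a <= land] <- NA_real_ # degenerate budget draws
    kappa <- stats::runif(n, kappa_range[1], kappa_range[2])
    theta <- stats::runif(n, theta_range[1], theta_range[2])
  }

  ok <- is.finite(f) & f > nep
  n_rejected <- sum(!ok)
  if (!any(ok)) stop("all Monte Carlo draws rejected", call. = FALSE)
  f <- f[ok]; kappa <- kappa[ok]; theta <- theta[ok]
  gpp <- (f + nep) / (0.88 * (theta * kappa + 1) + 1)
  fs <- gpp - nep

  out <- list(gpp = gpp, f_s = fs, f_land = f)
  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  summarise <- function(v) c(mean = mean(v), sd = stats::sd(v),
                             stats::quantile(v, qs, names = TRUE))
  summary <- do.call(rbind, lapply(out, summarise))
  summary <- data.frame(variable = rownames(summary), summary,
                        row.names = NULL, check.names = FALSE,
                        stringsAsFactors = FALSE)

  half <- seq_len(floor(length(gpp) / 2))
  convergence <- do.call(rbind, lapply(names(out), function(nm) {
    v <- out[[nm]]
    mc_se <- stats::sd(v) / sqrt(length(v))
    diff <- abs(mean(v) - mean(v[half]))
    data.frame(variable = nm, diff = diff, mc_se = mc_se,
               converged = diff <= 2 * mc_se, stringsAsFactors = FALSE)
  }))

  res <- list(summary = summary, n_draws = n, n_used = length(gpp),
              n_rejected = n_rejected,
              rejection_fraction = n_rejected / n,
              convergence = convergence, seed = as.integer(seed),
              mode = mode)
  if (keep_draws) {
    res$draws <- data.frame(f_land = f, kappa_c = kappa, theta_eq = theta,
                            gpp = gpp, f_s = fs)
  }
  structure(res, class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat("Monte Carlo uncertainty (mode =", x$mode, ", seed =", x$seed,
      ",", x$n_used, "of", x$n_draws, "draws used)\n")
  y <- x$summary
  y[-1] <- lapply(y[-1], round, 1)
  print.data.frame(y, row.names = FALSE, ...)
  if (x$n_rejected > 0) {
    cat(sprintf("rejected draws: %d (%.2f%%)\n", x$n_rejected,
                100 * x$rejection_fraction))
  }
  invisible(x)
}
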