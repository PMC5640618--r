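# Observational statistics on per-sample station measurement tables.
#
# The standard table has one row per flask/air sample with columns
#   site, datetime, co2_ppmv, d13C_permil, d18O_permil, d17O_permil,
#   D17O_permil
# (deltas in permil vs V-SMOW; d13C vs VPDB; D17O is the logarithmic
# anomaly at lambda = 0.516). d17O may be absent when D17O is supplied,
# and vice versa.

.measurement_columns <- c("site", "datetime", "co2_ppmv", "d13C_permil",
                          "d18O_permil", "d17O_permil", "D17O_permil")

#' Read / write station measurement tables
#'
#' Plain CSV with the documented columns. On read, a missing `d17O_permil`
#' is back-computed from `D17O_permil` (and vice versa); when both are
#' present, records where they disagree by more than 0.002 permil are
#' flagged with a warning, as are CO2 mixing ratios outside the (300, 600)
#' ppmv plausibility band.
#'
#' @param x a measurement `data.frame` (write) .
#' @param path CSV file path.
#' @return `read_measurements()` returns the completed `data.frame`;
#'   `write_measurements()` returns `path` invisibly.
#' @export
read_measurements <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- setdiff(.measurement_columns, c("d17O_permil", "D17O_permil"))
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("measurement table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  has_d17 <- "d17O_permil" %in% names(x) && any(is.finite(x$d17O_permil))
  has_cap <- "D17O_permil" %in% names(x) && any(is.finite(x$D17O_permil))
  if (!has_d17 && !has_cap) {
    stop("need at least one of d17O_permil, D17O_permil", call. = FALSE)
  }
  if (!has_cap) {
    x$D17O_permil <- cap_delta_log(x$d17O_permil, x$d18O_permil)
  } else if (!has_d17) {
    x$d17O_permil <- d17_from_cap_log(x$D17O_permil, x$d18O_permil)
  } else {
    gap <- abs(x$D17O_permil -
                 cap_delta_log(x$d17O_permil, x$d18O_permil))
    if (any(gap > 0.002, na.rm = TRUE)) {
      warning(sum(gap > 0.002, na.rm = TRUE),
              " record(s) with d17O/D17O inconsistency > 0.002 permil",
              call. = FALSE)
    }
  }
  out_of_band <- x$co2_ppmv <= 300 | x$co2_ppmv >= 600
  if (any(out_of_band, na.rm = TRUE)) {
    warning(sum(out_of_band, na.rm = TRUE),
            " record(s) outside the (300, 600) ppmv plausibility band",
            call. = FALSE)
  }
  x[, .measurement_columns]
}

#' @rdname read_measurements
#' @export
write_measurements <- function(x, path) {
  missing <- setdiff(.measurement_columns, names(x))
  if (length(missing)) {
    stop("measurement table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  utils::write.csv(x[, .measurement_columns], path, row.names = FALSE)
  invisible(path)
}

#' Per-site summary statistics
#'
#' Means, standard deviations and standard errors of the measured
#' variables, together with the triple-isotope regression (reduced major
#' axis and ordinary least squares of `ln(1+d17O)` on `ln(1+d18O)`) and
#' the mean log ratio. An optional delta-18O threshold excludes
#' low-delta-18O outliers from the regression and the log ratio only —
#' the means and spreads are always computed on the full record set.
#'
#' @param x a measurement `data.frame` (see [read_measurements()]).
#' @param d18_min optional threshold: records with `d18O_permil` below it
#'   are excluded from the regression and the log ratio.
#' @return a list of class `site_summary`: `site`, `n`, `stats` (per-
#'   variable n/mean/sd/se), `regression` (RMA and OLS fits),
#'   `log_ratio`, and `filter` (`d18_min`, `n_excluded`).
#' @export
site_summary <- function(x, d18_min = NULL) {
  if (nrow(x) < 2L) {
    stop("need at least 2 records for a site summary (sd undefined)",
         call. = FALSE)
  }
  vars <- c("co2_ppmv", "d13C_permil", "d18O_permil", "d17O_permil",
            "D17O_permil")
  stats_tab <- do.call(rbind, lapply(vars, function(v) {
    vv <- x[[v]][is.finite(x[[v]])]
    n <- length(vv)
    s <- if (n >= 2) stats::sd(vv) else NA_real_
    data.frame(variable = v, n = n, mean = mean(vv), sd = s,
               se = s / sqrt(n), stringsAsFactors = FALSE)
  }))

  keep <- if (is.null(d18_min)) rep(TRUE, nrow(x)) else
    x$d18O_permil >= d18_min
  xf <- x[keep, ]
  if (nrow(xf) < 3L) {
    stop("fewer than 3 records left after the d18O filter", call. = FALSE)
  }
  lx <- .log_permil(xf$d18O_permil)
  ly <- .log_permil(xf$d17O_permil)
  reg <- list(rma = gm_regression(lx, ly, method = "rma"),
              ols = gm_regression(lx, ly, method = "ols"))

  structure(list(site = if (length(unique(x$site)) == 1L) x$site[1] else
                   paste(unique(x$site), collapse = "+"),
                 n = nrow(x), stats = stats_tab, regression = reg,
                 log_ratio = mean_log_ratio(xf),
                 filter = list(d18_min = d18_min,
                               n_excluded = sum(!keep))),
            class = "site_summary")
}

#' @export
print.site_summary <- function(x, ...) {
  cat("Site summary:", x$site, "(n =", x$n, ")\n")
  y <- x$stats
  y$mean <- signif(y$mean, 6); y$sd <- signif(y$sd, 3)
  y$se <- signif(y$se, 3)
  print.data.frame(y, row.names = FALSE, ...)
  r <- x$regression$rma
  cat(sprintf("RMA slope %.4f +/- %.4f, intercept %.2f permil, R2 = %.3f",
              r$slope, r$slope_se, r$intercept, r$r2))
  if (x$filter$n_excluded > 0) {
    cat(sprintf(" (%d record(s) below d18O = %g excluded)",
                x$filter$n_excluded, x$filter$d18_min))
  }
  cat(sprintf("\nmean ln-ratio %.4f +/- %.4f\n", x$log_ratio$mean,
              x$log_ratio$se))
  invisible(x)
}

#' Unweighted multi-site average
#'
#' The global tropospheric anomaly is estimated as the unweighted mean of
#' the per-site mean anomalies (each site counting once regardless of its
#' sample count), with standard error `sd / sqrt(n_sites)`.
#'
#' @param site_means numeric vector of per-site means (permil), length
#'   >= 2.
#' @return a list with `mean`, `se` and `n`.
#' @examples
#' multi_site_average(c(0.335, 0.335, 0.31, 0.321))
#' @export
multi_site_average <- function(site_means) {
  if (length(site_means) < 2L || any(!is.finite(site_means))) {
    stop("need at least 2 finite site means", call. = FALSE)
  }
  n <- length(site_means)
  list(mean = mean(site_means),
       se = stats::sd(site_means) / sqrt(n), n = n)
}

#' Geometric-mean (reduced major axis) regression
#'
#' Symmetric line fit appropriate when both variables carry error:
#' slope = sign(r) * sd(y)/sd(x), line through the centroid. Swapping x
#' and y inverts the slope. An ordinary-least-squares mode is provided for
#' comparison. Slope standard errors use the standard large-sample formula
#' `|slope| * sqrt((1 - r^2) / (n - 2))` (identical for RMA and OLS).
#'
#' @param x,y numeric vectors, length >= 3; `x` must not be constant.
#' @param method `"rma"` (default) or `"ols"`.
#' @return a list with `slope`, `intercept`, `r2`, `slope_se`,
#'   `intercept_se`, `n`, `method`.
#' @export
gm_regression <- function(x, y, method = c("rma", "ols")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 finite (x, y) pairs", call. = FALSE)
  if (stats::sd(x) == 0) stop("x has zero variance", call. = FALSE)
  r <- stats::cor(x, y)
  slope <- if (method == "rma") {
    (if (r < 0) -1 else 1) * stats::sd(y) / stats::sd(x)
  } else {
    r * stats::sd(y) / stats::sd(x)
  }
  intercept <- mean(y) - slope * mean(x)
  slope_se <- abs(slope) * sqrt(max(0, 1 - r^2) / (n - 2))
  intercept_se <- slope_se *
    sqrt(sum(x^2) / n)
  list(slope = slope, intercept = intercept, r2 = r^2,
       slope_se = slope_se, intercept_se = intercept_se, n = n,
       method = method)
}

#' Mean per-record logarithmic isotope ratio
#'
#' Mean of `ln(1 + d17O) / ln(1 + d18O)` over the records, with its
#' standard error. For near-surface CO2 this ratio sits close to the
#' water-CO2 equilibrium exponent (0.5229).
#'
#' @param x a measurement `data.frame`; every record must have
#'   `d18O_permil != 0`.
#' @return a list with `mean`, `se` and `n`.
#' @export
mean_log_ratio <- function(x) {
  if (any(x$d18O_permil == 0)) {
    stop("log ratio undefined for records with d18O = 0", call. = FALSE)
  }
  ratio <- .log_permil(x$d17O_permil) / .log_permil(x$d18O_permil)
  n <- length(ratio)
  list(mean = mean(ratio),
       se = if (n >= 2) stats::sd(ratio) / sqrt(n) else NA_real_, n = n)
}

#' Rescale a measurement table to another lambda convention
#'
#' Applies [rescale_lambda()] record-wise to the anomaly column (the delta
#' columns are convention-free and unchanged). Used to place datasets
#' reported under different reference exponents on a common scale.
#'
#' @param x a measurement `data.frame` with per-record `d18O_permil`.
#' @param lambda_from,lambda_to source and target exponents.
#' @return the table with `D17O_permil` rescaled.
#' @export
rescale_dataset <- function(x, lambda_from, lambda_to) {
  if (any(!is.finite(x$d18O_permil))) {
    stop("per-record d18O required for rescaling", call. = FALSE)
  }
  x$D17O_permil <- rescale_lambda(x$D17O_permil, x$d18O_permil,
                                  lambda_from, lambda_to)
  x
}
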