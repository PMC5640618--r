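# Observational statistics on measurement tables.

make_table <- function(n = 60, seed = 4, slope = 0.518,
                       cap_target = 0.335) {
  generate_station(station_config("test", n, d18_mean = 40.65,
                                  d18_sd = 0.82, cap_target = cap_target,
                                  slope = slope), seed = seed)
}

test_that("site summary reports n, means and se = sd/sqrt(n)", {
  x <- make_table(200)
  s <- site_summary(x)
  expect_equal(s$n, 200)
  d18 <- s$stats[s$stats$variable == "d18O_permil", ]
  expect_equal(d18$se, d18$sd / sqrt(d18$n))
  expect_lt(abs(d18$mean - 40.65), 2 * d18$se + 0.05)
  cap <- s$stats[s$stats$variable == "D17O_permil", ]
  expect_lt(abs(cap$mean - 0.335), 2 * cap$se + 0.002)
  expect_error(site_summary(x[1, ]), "at least 2")
})

test_that("the d18O filter excludes exactly the records below threshold", {
  x <- make_table(150)
  x$d18O_permil[c(3, 9, 40)] <- c(38.4, 37.0, 38.49)
  x$d17O_permil <- d17_from_cap_log(x$D17O_permil, x$d18O_permil)
  s <- site_summary(x, d18_min = 38.5)
  expect_equal(s$filter$n_excluded, 3L)
  # means are computed on the full set, the regression on the filtered set
  expect_equal(s$stats$n[s$stats$variable == "d18O_permil"], 150)
  expect_equal(s$regression$rma$n, 147)
})

test_that("summary statistics are invariant under record order", {
  x <- make_table(80)
  s1 <- site_summary(x)
  s2 <- site_summary(x[sample.int(nrow(x)), ])
  expect_equal(s1$stats, s2$stats)
  expect_equal(s1$regression$rma$slope, s2$regression$rma$slope)
  expect_equal(s1$log_ratio$mean, s2$log_ratio$mean)
})

test_that("four-site average reproduces the published mean and its se", {
  avg <- multi_site_average(c(0.335, 0.335, 0.31, 0.321))
  expect_equal(avg$mean, 0.32525, tolerance = 1e-12)
  expect_gte(round(avg$mean, 3), 0.325)
  expect_equal(avg$se, 0.006, tolerance = 0.03)
  # two largest datasets only: about 0.004 below the published 0.326
  two <- multi_site_average(c(0.335, 0.31))
  expect_equal(two$mean, 0.3225)
  expect_equal(signif(0.326 - two$mean, 1), 0.004)
  # permutation invariance and the degenerate pair
  expect_equal(multi_site_average(c(0.31, 0.335, 0.321, 0.335))$mean,
               avg$mean)
  expect_equal(multi_site_average(c(0.3, 0.3)),
               list(mean = 0.3, se = 0, n = 2L))
  expect_error(multi_site_average(0.3), "at least 2")
})

test_that("RMA regression is exact on noise-free lines and symmetric", {
  x <- seq(38, 44, length.out = 20)
  y <- 0.516 * x
  fit <- gm_regression(x, y)
  expect_equal(fit$slope, 0.516, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$r2, 1)
  # swapping the axes inverts the RMA slope
  set.seed(8)
  yn <- y + rnorm(20, 0, 0.05)
  f1 <- gm_regression(x, yn)
  f2 <- gm_regression(yn, x)
  expect_equal(f2$slope, 1 / f1$slope, tolerance = 1e-12)
  expect_error(gm_regression(rep(1, 5), 1:5), "zero variance")
  expect_error(gm_regression(1:2, 1:2), "at least 3")
})

test_that("the generating slope is recovered from synthetic stations", {
  x <- make_table(455, seed = 12)
  s <- site_summary(x)
  fit <- s$regression$rma
  expect_lt(abs(fit$slope - 0.518), 2 * fit$slope_se)
  expect_lt(abs(fit$slope - 0.518), 0.002)  # bias bound at n = 455
  expect_gt(fit$r2, 0.98)
})

test_that("mean log ratio matches hand arithmetic and exact lines", {
  one <- data.frame(d17O_permil = 21, d18O_permil = 40)
  expect_equal(mean_log_ratio(one)$mean, 0.5298868253952103,
               tolerance = 1e-12)
  # records exactly on a 0.5229 line through the origin
  d18 <- seq(39, 43, length.out = 10)
  d17 <- 1000 * expm1(0.5229 * log1p(d18 / 1000))
  tab <- data.frame(d17O_permil = d17, d18O_permil = d18)
  expect_equal(mean_log_ratio(tab)$mean, 0.5229, tolerance = 1e-12)
  # synthetic near-surface data sit between the generating and
  # equilibrium slopes
  r <- site_summary(make_table(300, seed = 5))$log_ratio
  expect_gt(r$mean, 0.52); expect_lt(r$mean, 0.53)
  expect_error(mean_log_ratio(data.frame(d17O_permil = 1,
                                         d18O_permil = 0)),
               "d18O = 0")
})

test_that("dataset rescaling matches the scalar rule and round-trips", {
  x <- make_table(40)
  expect_equal(rescale_dataset(x, 0.516, 0.516), x)
  y <- rescale_dataset(x, 0.516, 0.528)
  expect_equal(y$D17O_permil,
               rescale_lambda(x$D17O_permil, x$d18O_permil, 0.516, 0.528))
  back <- rescale_dataset(y, 0.528, 0.516)
  expect_equal(back$D17O_permil, x$D17O_permil, tolerance = 1e-12)
})

test_that("measurement tables round-trip through CSV with completion", {
  x <- make_table(30)
  path <- tempfile(fileext = ".csv")
  write_measurements(x, path)
  y <- read_measurements(path)
  expect_equal(y$D17O_permil, x$D17O_permil, tolerance = 1e-9)
  # a table lacking d17O is completed from the anomaly
  x2 <- x
  x2$d17O_permil <- NA_real_
  utils::write.csv(x2, path, row.names = FALSE)
  y2 <- read_measurements(path)
  expect_equal(y2$d17O_permil, x$d17O_permil, tolerance = 1e-9)
  # inconsistent pairs and implausible CO2 are flagged
  x3 <- x
  x3$D17O_permil[1] <- x3$D17O_permil[1] + 0.01
  write_measurements(x3, path)
  expect_warning(read_measurements(path), "inconsistency")
  x4 <- x
  x4$co2_ppmv[2] <- 700
  write_measurements(x4, path)
  expect_warning(read_measurements(path), "plausibility")
})
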