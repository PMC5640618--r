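# Core triple-oxygen-isotope algebra: both anomaly conventions, convention
# conversion, lambda rescaling, water-CO2 equilibration and the
# transpiration relative-humidity term.

test_that("logarithmic anomaly matches direct evaluation and the identity", {
  expect_identical(cap_delta_log(0, 0, 0.516), 0)
  # frozen independent arithmetic at full precision
  expect_equal(cap_delta_log(21.107, 40.65, 0.516), 0.3270456601129972,
               tolerance = 1e-12)
  # a pair constructed exactly on the lambda = 0.528 reference line
  d18 <- 35
  d17 <- 1000 * expm1(0.528 * log1p(d18 / 1000))
  expect_equal(cap_delta_log(d17, d18, 0.528), 0, tolerance = 1e-12)
})

test_that("linear anomaly matches direct evaluation", {
  expect_identical(cap_delta_linear(0, 0, 0.516), 0)
  expect_equal(cap_delta_linear(21.746320987962253, 42, 0.516),
               0.07432098796225262, tolerance = 1e-12)
  # meteoric water: anomaly 0.032 permil at lambda = 0.528, d18O = -6.5
  d17 <- d17_from_cap_log(0.032, -6.5, 0.528)
  expect_equal(cap_delta_linear(d17, -6.5, 0.528), 0.0266089706364534,
               tolerance = 1e-10)
})

test_that("delta inputs are validated", {
  expect_error(cap_delta_log(NA_real_, 40), "finite")
  expect_error(cap_delta_log(-1000.5, 40), "physical bound")
  expect_error(cap_delta_log(0, 0, lambda = 0.6), "lambda")
})

test_that("log and linear conventions interconvert exactly", {
  expect_equal(log_to_linear(0.326, d18 = 41), 0.12712606619786726,
               tolerance = 1e-12)
  # anomaly of oceanic CO2 expressed on the budget scale
  expect_equal(log_to_linear(0.284, d18 = 42), 0.07432098796225262,
               tolerance = 1e-10)
  # at d18 = 0 the logarithms vanish to first order only through d17 = cap
  expect_equal(log_to_linear(0.3, d18 = 0),
               1000 * expm1(0.3 / 1000), tolerance = 1e-12)
  expect_error(log_to_linear(0.3), "d18")
  expect_error(linear_to_log(0.1), "d18")
})

test_that("log -> linear -> log round trip is the identity", {
  for (cap in c(-0.3, 0, 0.326, 2)) {
    for (d18 in c(-6.5, 0, 40.65, 42)) {
      expect_equal(linear_to_log(log_to_linear(cap, d18), d18), cap,
                   tolerance = 1e-9)
    }
  }
})

test_that("anomaly round-trips through the recovered delta-17O", {
  set.seed(42)
  d17 <- runif(50, -10, 45)
  d18 <- runif(50, -20, 50)
  cap <- cap_delta_log(d17, d18, 0.516)
  expect_equal(d17_from_cap_log(cap, d18, 0.516), d17, tolerance = 1e-10)
})

test_that("convention gap equals its closed form and vanishes at zero", {
  set.seed(7)
  d17 <- runif(20, -5, 45); d18 <- runif(20, -10, 50); lam <- 0.516
  gap <- cap_delta_linear(d17, d18, lam) - cap_delta_log(d17, d18, lam)
  expected <- (d17 - 1000 * log1p(d17 / 1000)) -
    lam * (d18 - 1000 * log1p(d18 / 1000))
  expect_equal(gap, expected, tolerance = 1e-12)
  expect_equal(cap_delta_linear(0, 0) - cap_delta_log(0, 0), 0)
})

test_that("lambda rescaling reproduces the meteoric and ocean water pairs", {
  # meteoric water: 0.032 permil on the 0.528 line maps to -0.046 at 0.516
  expect_equal(rescale_lambda(0.032, d18 = -6.5, 0.528, 0.516),
               -0.04625460388318563, tolerance = 1e-12)
  # ocean water: -0.005 at 0.528 maps to ~0.000 at 0.516
  expect_equal(rescale_lambda(-0.005, d18 = 0.42, 0.528, 0.516), 0,
               tolerance = 5e-5)
  # identity when source and target agree
  expect_identical(rescale_lambda(0.25, d18 = 37, 0.516, 0.516), 0.25)
})

test_that("rescaling composed there-and-back is the identity", {
  set.seed(11)
  cap <- runif(25, -0.5, 0.5); d18 <- runif(25, -10, 50)
  back <- rescale_lambda(rescale_lambda(cap, d18, 0.516, 0.528), d18,
                         0.528, 0.516)
  expect_equal(back, cap, tolerance = 1e-12)
})

test_that("water-CO2 equilibration reproduces both endmember anomalies", {
  land <- equilibrate_water_to_co2(-0.046, 1.043)
  expect_equal(land$cap_log, 0.2444981145285845, tolerance = 1e-12)
  ocean <- equilibrate_water_to_co2(0, 1.042, d18_water = 0.42)
  expect_equal(ocean$cap_log, 0.28387940898510966, tolerance = 1e-12)
  expect_equal(ocean$d18_co2, 1000 * (1.042 * 1.00042 - 1),
               tolerance = 1e-12)
  # alpha = 1 exchanges nothing
  expect_equal(equilibrate_water_to_co2(-0.046, 1)$cap_log, -0.046)
  expect_error(equilibrate_water_to_co2(0, -1), "positive")
})

test_that("equilibration has zero slope in its own convention", {
  for (alpha in c(1.01, 1.042, 1.043, 1.08)) {
    expect_equal(
      equilibrate_water_to_co2(0.1, alpha, lambda_ref = 0.5229)$cap_log,
      0.1, tolerance = 1e-12)
  }
})

test_that("transpiration shift is zero at 75% RH and linear around it", {
  expect_identical(transpiration_shift(0.75), 0)
  expect_equal(abs(transpiration_shift(0.80)), 0.015, tolerance = 1e-12)
  expect_equal(transpiration_shift(0.70), -0.015, tolerance = 1e-12)
  # continuity at the anchor
  eps <- 1e-9
  expect_lt(abs(transpiration_shift(0.75 + eps)), 1e-8)
  # error-budget variant
  expect_equal(abs(transpiration_shift(0.80, sensitivity = 0.017)), 0.017)
  expect_error(transpiration_shift(1.2), "fraction")
  expect_error(transpiration_shift(0), "fraction")
})
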