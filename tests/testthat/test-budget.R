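# Steady-state isoflux budget: solver, decomposition, curves and the
# kinetic-term bound.

test_that("default budget reproduces the headline flux and residence time", {
  sol <- solve_budget(budget_inputs())
  expect_equal(sol$f_land, 345, tolerance = 0.07)   # convention sensitivity
  expect_equal(round(sol$tau, 1), 1.9)
  expect_equal(sol$f_sur, sol$f_land + 90)
  # 2:1:1 terrestrial split
  expect_equal(sol$f_la, 2 * sol$f_r)
  expect_equal(sol$f_r, sol$f_s)
  expect_equal(sol$f_la + sol$f_r + sol$f_s, sol$f_land)
})

test_that("solver agrees with a brute-force root search to machine precision", {
  for (cap_a in c(0.30, 0.326, 0.36)) {
    inputs <- budget_inputs(cap_a_log = cap_a)
    expect_equal(solve_budget(inputs)$f_land, brute_force_f_land(inputs),
                 tolerance = 1e-10)
  }
})

test_that("hand-built budget matches independent arithmetic", {
  # endmembers chosen so the numerator is (50 - 4.5) and denominator 0.1
  em <- build_endmembers()
  em$cap_linear[em$name %in% c("leaf", "soil")] <- 0.02
  em$cap_linear[em$name == "ocean"] <- 0.07
  cap_a_lin <- 0.12
  inputs <- budget_inputs(cap_a_log = linear_to_log(cap_a_lin, 41),
                          f_anth = 0, endmembers = em)
  expect_equal(solve_budget(inputs)$f_land, (50 - 4.5) / 0.1,
               tolerance = 1e-9)
})

test_that("isofluxes balance and decompose as in the headline run", {
  sol <- solve_budget(budget_inputs())
  expect_lt(abs(sum(sol$isofluxes)), 1e-9)
  expect_equal(abs(sol$isofluxes[["terrestrial"]]), 42, tolerance = 0.02)
  expect_equal(abs(sol$isofluxes[["oceanic"]]), 5, tolerance = 0.1)
  expect_equal(sol$isofluxes[["stratospheric"]], 50)
  tab <- isoflux_table(sol)
  expect_equal(tab$isoflux[tab$source == "total"], 0, tolerance = 1e-9)
})

test_that("a stratospheric isoflux cancelling the others gives zero flux", {
  inputs <- budget_inputs()
  sol0 <- solve_budget(inputs)
  cancel <- -(sol0$isofluxes[["oceanic"]] +
                sol0$isofluxes[["anthropogenic"]])
  inputs$strat_isoflux <- cancel
  expect_equal(solve_budget(inputs)$f_land, 0, tolerance = 1e-9)
})

test_that("budget scales equivariantly with the fluxes", {
  inputs <- budget_inputs()
  base <- solve_budget(inputs)
  inputs2 <- budget_inputs(f_ao = 2 * inputs$f_ao,
                           f_anth = 2 * inputs$f_anth,
                           strat_isoflux = 2 * inputs$strat_isoflux)
  doubled <- solve_budget(inputs2)
  expect_equal(doubled$f_land, 2 * base$f_land, tolerance = 1e-12)
  expect_equal(doubled$tau, base$tau / 2, tolerance = 1e-12)
})

test_that("solution is insensitive to the assumed tropospheric d18O", {
  base <- solve_budget(budget_inputs())$f_land
  for (d18a in c(40.65, 41.25, 41.5)) {
    f <- solve_budget(budget_inputs(d18_a = d18a))$f_land
    expect_lt(abs(f - base), 25)
  }
})

test_that("degenerate and non-physical budgets raise structured errors", {
  expect_error(solve_budget(budget_inputs(cap_a_log = -0.5)),
               "degenerate")
  # without the stratospheric source the observed anomaly cannot be
  # balanced by any positive terrestrial flux
  expect_error(solve_budget(budget_inputs(cap_a_log = linear_to_log(0.1,
                                                                    41),
                                          strat_isoflux = 0)),
               "negative")
})

test_that("budget curves recover the headline row and are monotone", {
  inputs <- budget_inputs()
  grid <- seq(0.30, 0.36, by = 0.002)
  curves <- budget_curves(inputs, grid)
  expect_true(all(curves$flag == "ok"))
  i326 <- which(abs(grid - 0.326) < 1e-9)
  expect_equal(curves$f_land[i326], solve_budget(inputs)$f_land)
  expect_true(all(diff(curves$f_land) < 0))  # flux falls with the anomaly
  expect_true(all(diff(curves$tau) > 0))     # residence time rises
  # degenerate grid rows are flagged, not dropped
  flagged <- budget_curves(inputs, c(0.326, -0.5))
  expect_equal(nrow(flagged), 2L)
  expect_match(flagged$flag[2], "degenerate")
})

test_that("logarithmic diagnostic mode is labelled and differs", {
  lin <- solve_budget(budget_inputs())
  log <- solve_budget(budget_inputs(), convention = "logarithmic")
  expect_true(log$diagnostic)
  expect_false(lin$diagnostic)
  expect_gt(abs(log$f_land - lin$f_land), 1)
})

test_that("kinetic terms equal hand arithmetic and vanish at lambda_0", {
  kb <- kinetic_bound(c(leaf = 10, soil = 86, ocean = 90))
  expect_equal(kb$terms$term[kb$terms$pathway == "leaf"],
               10 * -7.4 * (0.529 - 0.516), tolerance = 1e-12)
  expect_equal(abs(kb$terms$term[kb$terms$pathway == "leaf"]), 0.962,
               tolerance = 1e-9)
  expect_equal(abs(kb$terms$term[kb$terms$pathway == "ocean"]),
               90 * 0.8 * 0.013, tolerance = 1e-9)
  zero <- kinetic_bound(c(leaf = 500, soil = 500, ocean = 500),
                        lambda = c(leaf = 0.516, soil = 0.516,
                                   ocean = 0.516))
  expect_identical(zero$total, 0)
  expect_error(kinetic_bound(c(leaf = 1, soil = 1, ocean = 1),
                             lambda = c(leaf = 0.54, soil = 0.52,
                                        ocean = 0.52)),
               "lambda")
})

test_that("forward anomaly and budget inversion are mutual inverses", {
  inputs <- budget_inputs()
  for (f_true in c(150, 345, 600)) {
    cap <- cap_a_from_f_land(f_true, inputs)
    inputs2 <- inputs
    inputs2$cap_a_log <- cap
    expect_equal(solve_budget(inputs2)$f_land, f_true, tolerance = 1e-8)
  }
})
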