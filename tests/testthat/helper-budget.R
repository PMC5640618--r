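# Shared fixtures: an independent brute-force route to the budget solution
# used as an oracle against the closed-form solver.

# residual of the steady-state isoflux balance at a candidate terrestrial
# flux, written directly from the balance equation (independent of
# solve_budget internals)
budget_residual <- function(f_land, inputs) {
  em <- inputs$endmembers
  cap_a <- log_to_linear(inputs$cap_a_log, inputs$d18_a)
  land <- (em$cap_linear[em$name == "leaf"] +
             em$cap_linear[em$name == "soil"]) / 2
  f_land * (land - cap_a) +
    inputs$f_ao * (em$cap_linear[em$name == "ocean"] - cap_a) +
    inputs$f_anth * (em$cap_linear[em$name == "anthropogenic"] - cap_a) +
    inputs$strat_isoflux
}

# brute-force 1-D root search for the terrestrial flux
brute_force_f_land <- function(inputs, interval = c(0, 5000)) {
  stats::uniroot(budget_residual, interval = interval, inputs = inputs,
                 tol = 1e-12)$root
}
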