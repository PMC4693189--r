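test_that("the diurnal optimum reproduces the example-model endpoints", {
  # scenario 1: 1 h of 1 M substrate, 1 h starvation, 0.1 M/h maintenance
  toy <- toy_pair()
  sol <- solve_diufba(build_extended_problem(toy$network, toy$config))
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 0.775, tolerance = 1e-9)
  expect_equal(unname(sol$transfers["STO"]), 0.125, tolerance = 1e-9)
  expect_equal(unname(sol$exports["BIO"]), 0.775, tolerance = 1e-9)

  # scenario 2: two hours of darkness double the storage demand
  toy2 <- toy_pair(dark_duration = 2)
  sol2 <- solve_diufba(build_extended_problem(toy2$network, toy2$config))
  expect_equal(unname(sol2$transfers["STO"]), 0.25, tolerance = 1e-9)
  expect_equal(unname(sol2$exports["BIO"]), 0.65, tolerance = 1e-9)
  expect_equal(sol2$objective_value, 0.65, tolerance = 1e-9)
})

test_that("with no carry-over the problem decouples into two FBAs", {
  # toy with transfers clamped to zero and maintenance removed: the
  # optimum equals the light-phase-only FBA
  sc <- toy_scenario(maintenance_rate = 0)
  toy <- build_toy_model(sc)
  cfg <- diurnal_config(
    phases = toy$config$phases,
    carryover_species = c("STO", "BIO"),
    exportable_species = "BIO",
    objective = c("export:BIO" = 1),
    transfer_bounds = list(STO = c(0, 0), BIO = c(0, Inf)))
  sol <- solve_diufba(build_extended_problem(toy$network, cfg))
  net_l <- diufba:::network_add_columns(
    toy$network, list(DM_bio = list(stoich = c(BIO = -1), lb = 0,
                                    ub = Inf, obj = 1)))
  fba <- fba_single_phase(net_l)
  expect_equal(sol$objective_value, fba$objective_value, tolerance = 1e-9)

  # randomized chain networks, p = 0: diurnal optimum = sum of the two
  # duration-weighted single-phase optima
  set.seed(11)
  for (rep in 1:20) {
    net <- random_chain_network(k = sample(3:5, 1))
    dt <- c(stats::runif(1, 0.5, 2), stats::runif(1, 0.5, 2))
    ex_dark <- stats::runif(1, 0, 1)
    cfg <- diurnal_config(
      phases = list(
        list(name = "light", duration = dt[1]),
        list(name = "dark", duration = dt[2],
             bounds = list(EX = c(0, ex_dark)))),
      carryover_species = character())
    sol <- solve_diufba(build_extended_problem(net, cfg))
    f1 <- fba_single_phase(net)
    f2 <- fba_single_phase(net, bound_overrides = list(EX = c(0, ex_dark)))
    expect_equal(sol$objective_value,
                 dt[1] * f1$objective_value + dt[2] * f2$objective_value,
                 tolerance = 1e-8)
  }
})

test_that("relaxing a transfer bound never decreases the optimum", {
  toy <- toy_pair()
  vals <- vapply(list(c(0, 0), c(0, 0.05), c(-Inf, Inf)), function(b) {
    cfg <- diurnal_config(
      phases = toy$config$phases,
      carryover_species = c("STO", "BIO"),
      exportable_species = "BIO",
      objective = c("export:BIO" = 1),
      transfer_bounds = list(STO = b))
    solve_diufba(build_extended_problem(toy$network, cfg))$objective_value
  }, numeric(1))
  expect_true(all(diff(vals) >= -1e-10))
  # known piecewise values: starving on biomass costs 1/e_bio = 2 per
  # maintenance unit, storage only 1/e_sto = 1.25
  expect_equal(vals, c(0.7, 0.7 + 0.6 * 0.05, 0.775), tolerance = 1e-9)
})

test_that("the optimum scales linearly with supply and maintenance", {
  base <- solve_diufba(build_extended_problem(
    toy_pair()$network, toy_pair()$config))$objective_value
  for (lam in c(0.5, 2)) {
    toy <- toy_pair(substrate_supply = lam, maintenance_rate = 0.1 * lam)
    sol <- solve_diufba(build_extended_problem(toy$network, toy$config))
    expect_equal(sol$objective_value, lam * base, tolerance = 1e-9)
  }
})

test_that("infeasibility is a status, not an exception", {
  toy <- toy_pair()
  cfg <- toy$config
  # no substrate in either phase but a hard maintenance demand
  cfg$phases[[1]]$bounds$EX_sub <- c(0, 0)
  sol <- solve_diufba(build_extended_problem(toy$network, cfg))
  expect_identical(sol$status, "infeasible")
  expect_true(is.na(sol$objective_value))
})

test_that("secondary flux minimization keeps the optimal objective", {
  toy <- toy_pair()
  prob <- build_extended_problem(toy$network, toy$config)
  plain <- solve_diufba(prob)
  parsim <- solve_diufba(prob, secondary = "min_total_flux")
  expect_equal(parsim$objective_value, plain$objective_value,
               tolerance = 1e-9)
  expect_lte(sum(abs(parsim$delta_c)), sum(abs(plain$delta_c)) + 1e-9)
  expect_lt(max(abs(as.vector(prob$S_ext %*% parsim$delta_c))), 1e-8)
})

test_that("single-phase FBA reproduces the greedy light-phase optimum", {
  toy <- toy_pair()
  # add a biomass drain so classical FBA can reward accumulation
  net <- diufba:::network_add_columns(
    toy$network, list(DM_bio = list(stoich = c(BIO = -1), lb = 0,
                                    ub = Inf, obj = 1)))
  fba <- fba_single_phase(net)
  expect_identical(fba$status, "optimal")
  expect_equal(fba$objective_value, 0.9, tolerance = 1e-9)

  # objective on a blocked reaction: zero flux, still optimal
  blocked <- fba_single_phase(net, bound_overrides = list(DM_bio = c(0, 0)),
                              objective = c(DM_bio = 1))
  expect_identical(blocked$status, "optimal")
  expect_equal(blocked$objective_value, 0, tolerance = 1e-12)

  # everything shut: objective 0 (maintenance relaxed so 0 is feasible)
  z <- build_toy_model(toy_scenario(maintenance_rate = 0))$network
  zeroed <- stats::setNames(rep(list(c(0, 0)), 8), z$reaction_ids)
  allzero <- fba_single_phase(z, bound_overrides = zeroed)
  expect_identical(allzero$status, "optimal")
  expect_equal(allzero$objective_value, 0)
})

test_that("transition composition matches the printed percentages", {
  toy <- toy_pair()
  sol <- solve_diufba(build_extended_problem(toy$network, toy$config))
  comp <- transition_composition(sol)
  expect_equal(sum(comp$fraction), 1, tolerance = 1e-12)
  expect_equal(round(100 * comp$fraction[comp$species == "BIO"], 1), 86.1)
  expect_equal(round(100 * comp$fraction[comp$species == "STO"], 1), 13.9)

  toy2 <- toy_pair(dark_duration = 2)
  comp2 <- transition_composition(
    solve_diufba(build_extended_problem(toy2$network, toy2$config)))
  expect_equal(round(100 * comp2$fraction[comp2$species == "BIO"], 1), 72.2)
  expect_equal(round(100 * comp2$fraction[comp2$species == "STO"], 1), 27.8)

  # all-functional: clamp the storage transfer to zero
  cfg <- diurnal_config(
    phases = toy$config$phases,
    carryover_species = c("STO", "BIO"),
    exportable_species = "BIO",
    objective = c("export:BIO" = 1),
    transfer_bounds = list(STO = c(0, 0)))
  comp3 <- transition_composition(
    solve_diufba(build_extended_problem(toy$network, cfg)))
  expect_equal(comp3$fraction[comp3$species == "BIO"], 1)
  expect_equal(comp3$fraction[comp3$species == "STO"], 0)

  # degenerate all-zero solution: fractions are undefined
  sc0 <- toy_scenario(maintenance_rate = 0)
  toy0 <- build_toy_model(sc0)
  cfg0 <- toy0$config
  cfg0$phases[[1]]$bounds$EX_sub <- c(0, 0)
  sol0 <- solve_diufba(build_extended_problem(toy0$network, cfg0))
  expect_identical(sol0$status, "optimal")
  expect_error(transition_composition(sol0), "undefined")
})
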