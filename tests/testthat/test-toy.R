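test_that("the closed-form optimum gives the documented values", {
  o1 <- toy_oracle(toy_scenario())
  expect_equal(o1$storage, 0.125)
  expect_equal(o1$biomass, 0.775)
  o2 <- toy_oracle(toy_scenario(dark_duration = 2))
  expect_equal(o2$storage, 0.25)
  expect_equal(o2$biomass, 0.65)
  expect_equal(round(100 * unname(o2$fractions), 1), c(72.2, 27.8))
  # no night, no storage
  o0 <- toy_oracle(toy_scenario(dark_duration = 0))
  expect_equal(o0$storage, 0)
  expect_equal(o0$biomass, 0.9)
  # a night too long to be survivable is flagged
  expect_false(toy_oracle(toy_scenario(dark_duration = 10))$feasible)
})

test_that("scenario parameters are validated", {
  expect_error(toy_scenario(e_sto = 0.4, e_bio = 0.5), "e_bio <= e_sto")
  expect_error(toy_scenario(e_sto = 1.2), "e_sto <= 1")
  expect_error(toy_scenario(substrate_supply = 0))
  expect_error(build_toy_model(toy_scenario(dark_duration = 0)),
               "dark_duration")
  toy <- build_toy_model(toy_scenario())
  expect_equal(dim(toy$network), c(4L, 8L))
  # supply only exists during the day
  expect_equal(toy$config$phases[[2]]$bounds$EX_sub, c(0, 0))
})

test_that("LP and closed form agree across a parameter sweep", {
  grid <- expand.grid(supply = seq(0.5, 2, length.out = 5),
                      dtd = c(0.5, 1, 2, 4),
                      e_sto = c(0.6, 0.8, 0.95))
  expect_gte(nrow(grid), 50)
  for (i in seq_len(nrow(grid))) {
    sc <- toy_scenario(substrate_supply = grid$supply[i],
                       dark_duration = grid$dtd[i],
                       e_sto = grid$e_sto[i])
    oracle <- toy_oracle(sc)
    toy <- build_toy_model(sc)
    sol <- solve_diufba(build_extended_problem(toy$network, toy$config))
    if (!oracle$feasible) {
      # storage cannot cover the night even using the whole supply, and
      # every other route is dearer still: the LP must agree
      expect_identical(sol$status, "infeasible")
    } else {
      expect_identical(sol$status, "optimal")
      expect_equal(sol$objective_value, oracle$objective, tolerance = 1e-9)
      expect_equal(unname(sol$transfers["STO"]), oracle$storage,
                   tolerance = 1e-9)
    }
  }
})

test_that("the lossless limit converts every substrate into biomass", {
  sc <- toy_scenario(e_sto = 1, e_bio = 1)
  toy <- build_toy_model(sc)
  sol <- solve_diufba(build_extended_problem(toy$network, toy$config))
  expect_equal(sol$objective_value,
               sc$substrate_supply - sc$maintenance_rate *
                 (sc$light_duration + sc$dark_duration),
               tolerance = 1e-9)
})

test_that("the sequential comparator is myopic and starves at night", {
  toy <- toy_pair()
  run <- dfba_soa(toy$network, toy$config)
  expect_identical(run$status, "optimal")
  traj <- run$trajectory
  # greedy day: all substrate into biomass, none stored
  expect_equal(traj$after_phase1[traj$species == "BIO"], 0.9,
               tolerance = 1e-9)
  expect_equal(traj$after_phase1[traj$species == "STO"], 0,
               tolerance = 1e-9)
  # night maintenance burns biomass at efficiency 0.5
  expect_equal(run$final_functional, 0.7, tolerance = 1e-9)

  toy2 <- toy_pair(dark_duration = 2)
  expect_equal(dfba_soa(toy2$network, toy2$config)$final_functional, 0.5,
               tolerance = 1e-9)

  # without maintenance nothing is consumed
  toy0 <- build_toy_model(toy_scenario(maintenance_rate = 0))
  expect_equal(dfba_soa(toy0$network, toy0$config)$final_functional, 1,
               tolerance = 1e-9)

  # a night the greedy pools cannot survive collapses
  toyhard <- build_toy_model(toy_scenario(maintenance_rate = 0.6))
  expect_identical(dfba_soa(toyhard$network, toyhard$config)$status,
                   "starvation-collapse")
})

test_that("foresight dominates the sequential strategy", {
  set.seed(23)
  strict <- 0L
  for (rep in 1:12) {
    sc <- toy_scenario(substrate_supply = stats::runif(1, 0.8, 2),
                       dark_duration = sample(c(0.5, 1, 2), 1),
                       e_sto = stats::runif(1, 0.55, 0.95),
                       e_bio = 0.5)
    if (!toy_oracle(sc)$feasible) next
    toy <- build_toy_model(sc)
    diu <- solve_diufba(build_extended_problem(toy$network, toy$config))
    seq_run <- dfba_soa(toy$network, toy$config)
    if (!identical(seq_run$status, "optimal")) next
    expect_gte(diu$objective_value, seq_run$final_functional - 1e-9)
    if (diu$objective_value > seq_run$final_functional + 1e-9)
      strict <- strict + 1L
    # storage is strictly cheaper than starvation whenever e_sto < 1
    if (sc$e_sto < 1) expect_gt(diu$objective_value,
                                seq_run$final_functional)
  }
  expect_gt(strict, 0L)
})

test_that("storage share at the transition grows with the night length", {
  shares <- vapply(c(0.5, 1, 2, 3), function(dtd) {
    toy <- toy_pair(dark_duration = dtd)
    comp <- transition_composition(
      solve_diufba(build_extended_problem(toy$network, toy$config)))
    comp$fraction[comp$species == "STO"]
  }, numeric(1))
  expect_true(all(diff(shares) > 0))
})
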