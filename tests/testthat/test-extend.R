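test_that("transfer and export matrices have the documented structure", {
  toy <- toy_pair()
  Tm <- build_transfer_matrix(toy$network, toy$config)
  expect_equal(dim(Tm), c(8L, 2L))
  s <- length(toy$network$species_ids)
  for (sp in c("STO", "BIO")) {
    col <- Tm[, paste0("transfer:", sp)]
    i <- match(sp, toy$network$species_ids)
    expect_equal(unname(col[i]), -1)       # out of the light balance
    expect_equal(unname(col[i + s]), 1)    # into the dark balance
    expect_equal(sum(col != 0), 2)
  }
  Em <- build_export_matrix(toy$network, toy$config)
  expect_equal(dim(Em), c(8L, 1L))
  i <- match("BIO", toy$network$species_ids)
  expect_equal(unname(Em[i + s, 1]), -1)
  expect_equal(sum(Em != 0), 1)

  # empty carryover list: a 2s x 0 matrix, phases fully decoupled
  cfg0 <- diurnal_config(phases = toy$config$phases,
                         carryover_species = character())
  expect_equal(dim(build_transfer_matrix(toy$network, cfg0)), c(8L, 0L))
  expect_equal(dim(build_export_matrix(toy$network, cfg0)), c(8L, 0L))
})

test_that("extended problem assembles block-diagonally with scaled bounds", {
  toy <- toy_pair()
  prob <- build_extended_problem(toy$network, toy$config)
  expect_equal(dim(prob$S_ext), c(8L, 19L))  # 2*8 + 2 transfer + 1 export

  # block fidelity: each phase block reproduces S exactly, zero elsewhere
  cm <- prob$col_map
  S <- as.matrix(toy$network$stoich)
  for (ph in c("light", "dark")) {
    cols <- which(cm$kind == "reaction" & cm$phase == ph)
    rows <- if (ph == "light") 1:4 else 5:8
    blk <- as.matrix(prob$S_ext[, cols])
    expect_equal(unname(blk[rows, ]), unname(S))
    expect_true(all(blk[-rows, ] == 0))
  }

  # Euler scaling: concentration-change bounds are flux bounds times the
  # phase duration; equalities stay equalities
  i_mnt_dark <- which(cm$label == "dark:DM_mnt")
  expect_equal(prob$v_lb_ext[i_mnt_dark], 0.1)
  expect_equal(prob$v_ub_ext[i_mnt_dark], 0.1)
  toy2 <- toy_pair(dark_duration = 2)
  prob2 <- build_extended_problem(toy2$network, toy2$config)
  cm2 <- prob2$col_map
  expect_equal(prob2$v_lb_ext[cm2$label == "dark:DM_mnt"], 0.2)
  expect_equal(prob2$v_ub_ext[cm2$label == "dark:DM_mnt"], 0.2)
  # doubling the dark duration doubles only dark reaction bounds
  dark2 <- cm2$kind == "reaction" & cm2$phase == "dark"
  dark1 <- cm$kind == "reaction" & cm$phase == "dark"
  expect_equal(prob2$v_ub_ext[dark2][is.finite(prob2$v_ub_ext[dark2])],
               2 * prob$v_ub_ext[dark1][is.finite(prob$v_ub_ext[dark1])])
  expect_equal(prob2$v_ub_ext[cm2$phase %in% "light"],
               prob$v_ub_ext[cm$phase %in% "light"])

  # transfers unbounded both directions, exports nonnegative
  expect_true(all(prob$v_lb_ext[cm$kind == "transfer"] == -Inf))
  expect_true(all(prob$v_ub_ext[cm$kind == "transfer"] == Inf))
  expect_equal(prob$v_lb_ext[cm$kind == "export"], 0)

  # minimal model, no coupling: pure block diagonal
  S1 <- Matrix::sparseMatrix(i = 1, j = 1, x = -1,
                             dimnames = list("A", "sink"))
  net1 <- metabolic_network(S1, lb = 0, ub = 1)
  cfg1 <- diurnal_config(
    phases = list(list(name = "light", duration = 1),
                  list(name = "dark", duration = 1)),
    carryover_species = character())
  p1 <- build_extended_problem(net1, cfg1)
  expect_equal(as.matrix(p1$S_ext),
               matrix(c(-1, 0, 0, -1), 2, 2,
                      dimnames = list(c("light:A", "dark:A"),
                                      c("light:sink", "dark:sink"))))

  cfg3 <- diurnal_config(
    phases = list(list(name = "a", duration = 1),
                  list(name = "b", duration = 1),
                  list(name = "c", duration = 1)),
    carryover_species = character())
  expect_error(build_extended_problem(net1, cfg3), "2 phases")
})

test_that("phase fluxes invert the duration scaling", {
  toy <- toy_pair(dark_duration = 2)
  prob <- build_extended_problem(toy$network, toy$config)
  v <- numeric(19)
  cm <- prob$col_map
  v[cm$label == "dark:DM_mnt"] <- 0.2
  v[cm$label == "light:R_bio"] <- 0.5
  v[cm$label == "transfer:STO"] <- 0.125
  pf <- phase_fluxes(v, prob)
  expect_equal(unname(pf$dark["DM_mnt"]), 0.1)     # 0.2 over 2 h
  expect_equal(unname(pf$light["R_bio"]), 0.5)     # 1 h: identity
  expect_equal(unname(pf$transfers["STO"]), 0.125) # amounts, unscaled
  expect_error(phase_fluxes(numeric(5), prob), "length")
})

test_that("solved optima satisfy per-species conservation across phases", {
  toy <- toy_pair()
  prob <- build_extended_problem(toy$network, toy$config)
  sol <- solve_diufba(prob)
  expect_identical(sol$status, "optimal")
  # overall mass balance
  expect_lt(max(abs(as.vector(prob$S_ext %*% sol$delta_c))), 1e-9)
  cm <- prob$col_map
  S <- toy$network$stoich
  light_prod <- as.vector(S %*% sol$delta_c[cm$kind == "reaction" &
                                            cm$phase == "light"])
  dark_prod <- as.vector(S %*% sol$delta_c[cm$kind == "reaction" &
                                           cm$phase == "dark"])
  names(light_prod) <- names(dark_prod) <- toy$network$species_ids
  for (sp in c("STO", "BIO")) {
    ex <- if (sp %in% names(sol$exports)) sol$exports[[sp]] else 0
    # net light production leaves via the transfer column ...
    expect_equal(light_prod[[sp]], sol$transfers[[sp]], tolerance = 1e-9)
    # ... and what arrives at night is consumed or exported
    expect_equal(sol$transfers[[sp]], -dark_prod[[sp]] + ex,
                 tolerance = 1e-9)
  }
  # the 0.125 M storage transfer moves mass out of the light balance
  expect_equal(sol$transfers[["STO"]], 0.125, tolerance = 1e-9)
})

test_that("extended problems serialize to MatrixMarket plus a column map", {
  toy <- toy_pair()
  prob <- build_extended_problem(toy$network, toy$config)
  prefix <- tempfile()
  paths <- write_extended_problem(prob, prefix)
  back <- Matrix::readMM(paste0(prefix, ".mtx"))
  expect_equal(unname(as.matrix(back)), unname(as.matrix(prob$S_ext)))
  cmap <- utils::read.delim(paste0(prefix, "_columns.tsv"))
  expect_equal(nrow(cmap), 19L)
  expect_true(all(c("kind", "lb", "ub", "objective_weight") %in%
                  names(cmap)))
})
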