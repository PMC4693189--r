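#' Parameters of the two-phase example model
#'
#' A minimal network demonstrating diurnal resource allocation: a
#' substrate (photons, in a photosynthetic reading) supplied only during
#' the light phase can be spent on functional biomass, on a storage
#' metabolite, or directly on maintenance. During the dark phase
#' maintenance must be covered from storage (efficiency \code{e_sto}) or,
#' as starvation, from biomass itself (efficiency \code{e_bio}), with
#' \code{e_bio <= e_sto}: the storage metabolite is the less, biomass the
#' least efficient maintenance substrate.
#'
#' Default efficiencies are calibrated from the scenario-1 bookkeeping:
#' covering 0.1 M/h maintenance for 1 h by consuming 0.2 M biomass gives
#' \code{e_bio = 0.5}; covering it with 0.125 M of storage gives
#' \code{e_sto = 0.8}. Substrate conversions are 1:1.
#'
#' @param light_duration,dark_duration phase lengths in hours
#'   (\code{dark_duration = 0} is allowed for the degenerate no-night
#'   limit of the closed-form optimum).
#' @param substrate_supply total substrate available during the light
#'   phase (M per phase).
#' @param maintenance_rate fixed maintenance demand (M/h), enforced as an
#'   equality in every phase.
#' @param e_sto,e_bio maintenance/growth yield per unit of storage
#'   metabolite and of biomass; require \code{0 < e_bio <= e_sto <= 1}.
#' @return object of class \code{toy_scenario}.
#' @export
toy_scenario <- function(light_duration = 1, dark_duration = 1,
                         substrate_supply = 1, maintenance_rate = 0.1,
                         e_sto = 0.8, e_bio = 0.5) {
  stopifnot(light_duration > 0, dark_duration >= 0,
            substrate_supply > 0, maintenance_rate >= 0)
  if (!(e_bio > 0 && e_bio <= e_sto && e_sto <= 1))
    stop("efficiencies must satisfy 0 < e_bio <= e_sto <= 1")
  structure(list(light_duration = light_duration,
                 dark_duration = dark_duration,
                 substrate_supply = substrate_supply,
                 maintenance_rate = maintenance_rate,
                 e_sto = e_sto, e_bio = e_bio),
            class = "toy_scenario")
}

#' Build the example model and its diurnal configuration
#'
#' Species: \code{SUB} (substrate), \code{STO} (storage metabolite),
#' \code{BIO} (functional biomass, in molar precursor units), \code{MNT}
#' (maintenance sink). Eight reactions: substrate supply \code{EX_sub}
#' (shut off in the dark phase), conversions \code{R_bio}, \code{R_sto},
#' \code{R_m_sub} (all 1:1), storage-fuelled maintenance and growth
#' \code{R_m_sto}, \code{R_g_sto} (yield \code{e_sto}), starvation
#' \code{R_m_bio} (yield \code{e_bio}), and the maintenance demand
#' \code{DM_mnt}, an equality at the maintenance rate. \code{STO} and
#' \code{BIO} are carried over to the night; \code{BIO} is exportable and
#' carries the objective.
#'
#' @param scenario a \code{\link{toy_scenario}}.
#' @return list with elements \code{network} and \code{config}.
#' @export
build_toy_model <- function(scenario = toy_scenario()) {
  stopifnot(inherits(scenario, "toy_scenario"))
  if (scenario$dark_duration <= 0)
    stop("building the two-phase model requires dark_duration > 0")
  sc <- scenario
  supply_rate <- sc$substrate_supply / sc$light_duration
  eq <- c(EX_sub   = "-> SUB",
          R_bio    = "SUB -> BIO",
          R_sto    = "SUB -> STO",
          R_m_sub  = "SUB -> MNT",
          R_m_sto  = sprintf("STO -> %.15g MNT", sc$e_sto),
          R_g_sto  = sprintf("STO -> %.15g BIO", sc$e_sto),
          R_m_bio  = sprintf("BIO -> %.15g MNT", sc$e_bio),
          DM_mnt   = "MNT ->")
  terms <- lapply(names(eq), function(id) parse_equation(eq[[id]], id))
  species <- unique(unlist(lapply(terms, names)))
  S <- Matrix::sparseMatrix(
    i = unlist(lapply(terms, function(tt) match(names(tt), species))),
    j = rep(seq_along(terms), lengths(terms)),
    x = unlist(terms), dims = c(length(species), length(eq)),
    dimnames = list(species, names(eq)))
  lb <- c(0, 0, 0, 0, 0, 0, 0, sc$maintenance_rate)
  ub <- c(supply_rate, Inf, Inf, Inf, Inf, Inf, Inf, sc$maintenance_rate)
  network <- metabolic_network(S, lb = lb, ub = ub)
  config <- diurnal_config(
    phases = list(
      list(name = "light", duration = sc$light_duration),
      list(name = "dark", duration = sc$dark_duration,
           bounds = list(EX_sub = c(0, 0)))),
    carryover_species = c("STO", "BIO"),
    exportable_species = "BIO",
    objective = c("export:BIO" = 1))
  list(network = network, config = config, scenario = scenario)
}

#' Closed-form optimum of the example model
#'
#' Independent of the LP machinery, the optimum follows from direct
#' resource accounting: night maintenance (\code{maintenance_rate *
#' dark_duration}) is covered most cheaply by storage, so the optimal
#' storage amount is that demand divided by \code{e_sto}; everything else
#' left after light-phase maintenance becomes functional biomass.
#'
#' @param scenario a \code{\link{toy_scenario}}.
#' @return list with \code{storage}, \code{biomass}, \code{objective}
#'   (equal to \code{biomass}), \code{fractions} (functional, storage at
#'   the transition) and \code{feasible}.
#' @examples
#' toy_oracle(toy_scenario())$storage        # 0.125
#' toy_oracle(toy_scenario(dark_duration = 2))$fractions
#' @export
toy_oracle <- function(scenario = toy_scenario()) {
  stopifnot(inherits(scenario, "toy_scenario"))
  sc <- scenario
  storage <- sc$maintenance_rate * sc$dark_duration / sc$e_sto
  biomass <- sc$substrate_supply -
    sc$maintenance_rate * sc$light_duration - storage
  feasible <- biomass >= -1e-12
  total <- biomass + storage
  list(storage = storage, biomass = biomass, objective = biomass,
       fractions = if (feasible && total > 0)
         c(functional = biomass / total, storage = storage / total),
       feasible = feasible)
}

#' Sequential (static-optimization) dynamic FBA comparator
#'
#' Solves the diurnal cycle as two myopic LPs: the light phase greedily
#' maximizes the accumulation of functional biomass with no lookahead;
#' the end-of-phase pool amounts of all carry-over species then become
#' bounded supplies for the dark phase, which maximizes the final
#' functional biomass. Because the first step cannot anticipate the
#' night, no storage metabolites are laid down and maintenance must be
#' covered by consuming biomass (starvation).
#'
#' @param network,config as from \code{\link{build_toy_model}} (any
#'   two-phase model whose carry-over species identify the pools works).
#' @return object of class \code{dfba_soa}: \code{status}
#'   (\code{"optimal"} or \code{"starvation-collapse"}),
#'   \code{trajectory} (pool amounts per species at phase boundaries),
#'   \code{final_functional}.
#' @examples
#' toy <- build_toy_model(toy_scenario())
#' dfba_soa(toy$network, toy$config)$final_functional   # 0.7
#' @export
dfba_soa <- function(network, config) {
  validate_config(config, network)
  if (length(config$phases) != 2L)
    stop("the sequential comparator supports exactly 2 phases")
  pools <- config$carryover_species
  functional <- names(config$component_labels)[
    config$component_labels == "functional"]
  s_idx <- match(pools, network$species_ids)

  phase_lp <- function(ph, src_ub) {
    lo <- network$lb; hi <- network$ub
    for (rid in names(ph$bounds)) {
      lo[rid] <- ph$bounds[[rid]][1]; hi[rid] <- ph$bounds[[rid]][2]
    }
    np <- length(pools)
    S <- network$stoich
    s <- nrow(S)
    acc <- Matrix::sparseMatrix(i = s_idx, j = seq_len(np), x = -1,
                                dims = c(s, np))
    src <- Matrix::sparseMatrix(i = s_idx, j = seq_len(np), x = +1,
                                dims = c(s, np))
    A <- cbind(S, acc, src)
    r <- ncol(S)
    obj <- c(numeric(r),
             as.numeric(pools %in% functional),          # reward final pool
             -as.numeric(pools %in% functional))         # penalize drawdown
    res <- lp_simplex(obj, A, rhs = 0,
                      lb = c(lo * ph$duration, numeric(2 * np)),
                      ub = c(hi * ph$duration, rep(Inf, np), src_ub),
                      maximize = TRUE)
    if (res$status == "optimal") {
      res$acc <- stats::setNames(res$x[r + seq_len(np)], pools)
      res$src <- stats::setNames(res$x[r + np + seq_len(np)], pools)
    }
    res
  }

  pool0 <- stats::setNames(numeric(length(pools)), pools)
  p1 <- phase_lp(config$phases[[1]], src_ub = pool0)
  if (p1$status != "optimal")
    return(structure(list(status = p1$status, trajectory = NULL,
                          final_functional = NA_real_),
                     class = "dfba_soa"))
  pool1 <- p1$acc - p1$src
  p2 <- phase_lp(config$phases[[2]], src_ub = pool1)
  if (p2$status != "optimal")
    return(structure(list(
      status = "starvation-collapse",
      trajectory = data.frame(species = pools, start = pool0,
                              after_phase1 = pool1, after_phase2 = NA_real_),
      final_functional = NA_real_), class = "dfba_soa"))
  pool2 <- pool1 - p2$src + p2$acc
  structure(list(
    status = "optimal",
    trajectory = data.frame(species = pools, start = unname(pool0),
                            after_phase1 = unname(pool1),
                            after_phase2 = unname(pool2),
                            stringsAsFactors = FALSE),
    final_functional = sum(pool2[pools %in% functional]),
    phase_objectives = c(p1$objective, p2$objective)),
    class = "dfba_soa")
}

#' @export
print.dfba_soa <- function(x, ...) {
  cat("Sequential dFBA (static optimization) — status:", x$status, "\n")
  if (!is.null(x$trajectory)) print(x$trajectory, row.names = FALSE)
  if (is.finite(x$final_functional))
    cat(sprintf("  final functional biomass: %.6g\n", x$final_functional))
  invisible(x)
}

#' Run the example model end to end
#'
#' Convenience wrapper used by the command-line front end: builds the
#' example model for a named scenario and runs either the diurnal LP or
#' the sequential comparator.
#'
#' @param scenario \code{1} (1 h light / 1 h dark), \code{2} (1 h light /
#'   2 h dark), or a \code{\link{toy_scenario}}.
#' @param method \code{"diufba"} or \code{"dfba-soa"}.
#' @return a summary list (method, status, per-phase amounts, transition
#'   composition for the diurnal method, final functional biomass).
#' @export
run_toy <- function(scenario = 1, method = c("diufba", "dfba-soa")) {
  method <- match.arg(method)
  if (!inherits(scenario, "toy_scenario")) {
    stopifnot(scenario %in% c(1, 2))
    scenario <- toy_scenario(dark_duration = as.numeric(scenario))
  }
  toy <- build_toy_model(scenario)
  if (method == "dfba-soa") {
    run <- dfba_soa(toy$network, toy$config)
    list(method = method, status = run$status,
         trajectory = run$trajectory,
         final_functional = run$final_functional)
  } else {
    sol <- solve_diufba(build_extended_problem(toy$network, toy$config))
    comp <- if (identical(sol$status, "optimal"))
      transition_composition(sol)
    list(method = method, status = sol$status,
         objective = sol$objective_value,
         transfers = as.list(sol$transfers),
         exports = as.list(sol$exports),
         composition = comp,
         final_functional = if (identical(sol$status, "optimal"))
           unname(sol$exports["BIO"]) else NA_real_)
  }
}
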