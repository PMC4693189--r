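#' Solve the diurnal flux balance problem
#'
#' Maximizes the weighted objective \code{w' v} over the extended
#' variable vector subject to mass balance \code{S_ext v = 0} and the
#' time-integrated bounds. Infeasibility and unboundedness are reported
#' in the \code{status} field, never as errors.
#'
#' With \code{secondary = "min_total_flux"} a second LP minimizes the
#' total absolute concentration change at the fixed optimal objective
#' value, as a control against alternate optima.
#'
#' @param problem an \code{\link{build_extended_problem}} result.
#' @param secondary \code{"none"} (default) or \code{"min_total_flux"}.
#' @param tol feasibility tolerance (relative to solution magnitude).
#' @return an object of class \code{diufba_solution}: \code{status},
#'   \code{objective_value}, \code{delta_c} (named extended vector),
#'   \code{transfers}, \code{exports} (amounts per species),
#'   \code{fluxes} (per-phase rates, see \code{\link{phase_fluxes}}),
#'   \code{residual}.
#' @examples
#' toy <- build_toy_model(toy_scenario())
#' sol <- solve_diufba(build_extended_problem(toy$network, toy$config))
#' sol$transfers   # storage laid down for the night
#' @export
solve_diufba <- function(problem, secondary = c("none", "min_total_flux"),
                         tol = 1e-9) {
  secondary <- match.arg(secondary)
  stopifnot(inherits(problem, "extended_problem"))
  res <- lp_simplex(problem$w, problem$S_ext, rhs = 0,
                    lb = problem$v_lb_ext, ub = problem$v_ub_ext,
                    maximize = TRUE, tol = tol)
  if (res$status == "failed")
    stop("LP solver failure after ", res$iter,
         " pivots; constraint residual: ", format(res$residual))
  if (res$status != "optimal")
    return(structure(list(status = res$status,
                          objective_value = NA_real_,
                          delta_c = NULL, transfers = NULL,
                          exports = NULL, fluxes = NULL,
                          residual = NA_real_, problem = problem),
                     class = "diufba_solution"))
  x <- res$x
  if (secondary == "min_total_flux")
    x <- minimize_total_flux(problem, res$objective, tol)
  pf <- phase_fluxes(x, problem)
  structure(list(
    status = "optimal",
    objective_value = sum(problem$w * x),
    delta_c = stats::setNames(x, problem$col_map$label),
    transfers = pf$transfers,
    exports = pf$exports,
    fluxes = pf[names(problem$phase_durations)],
    residual = max(abs(as.vector(problem$S_ext %*% x))),
    problem = problem), class = "diufba_solution")
}

## second-stage LP: min sum |v| at fixed objective value, via variable
## splitting v = v+ - v-
minimize_total_flux <- function(problem, opt, tol) {
  A <- as.matrix(problem$S_ext)
  n <- ncol(A)
  lb <- problem$v_lb_ext; ub <- problem$v_ub_ext
  Asplit <- rbind(cbind(A, -A), c(problem$w, -problem$w))
  lbp <- pmax(lb, 0); ubp <- pmax(ub, 0)
  lbn <- pmax(-ub, 0); ubn <- pmax(-lb, 0)
  res <- lp_simplex(rep(1, 2 * n), Asplit, rhs = c(numeric(nrow(A)), opt),
                    lb = c(lbp, lbn), ub = c(ubp, ubn),
                    maximize = FALSE, tol = tol)
  if (res$status != "optimal")
    stop("secondary flux-minimization LP returned status ", res$status)
  res$x[seq_len(n)] - res$x[n + seq_len(n)]
}

#' @export
print.diufba_solution <- function(x, ...) {
  cat("diuFBA solution — status:", x$status, "\n")
  if (x$status == "optimal") {
    cat(sprintf("  objective value: %.6g\n", x$objective_value))
    if (length(x$transfers)) {
      cat("  transfers (light -> dark):\n")
      for (sp in names(x$transfers))
        cat(sprintf("    %-12s %.6g\n", sp, x$transfers[[sp]]))
    }
    if (length(x$exports)) {
      cat("  exports (leaving the cycle):\n")
      for (sp in names(x$exports))
        cat(sprintf("    %-12s %.6g\n", sp, x$exports[[sp]]))
    }
  }
  invisible(x)
}

#' Classical single-phase flux balance analysis
#'
#' Standard FBA over one set of environmental conditions:
#' \code{max obj' v} subject to \code{S v = 0} and bounds. Used as the
#' decoupling oracle for the diurnal problem and as the per-step LP of
#' the sequential dynamic-FBA comparator.
#'
#' @param network a \code{metabolic_network}.
#' @param bound_overrides named list \code{reaction_id -> c(lb, ub)}.
#' @param objective named numeric over reaction ids, or \code{NULL} to
#'   use the model's own objective coefficients.
#' @param tol LP tolerance.
#' @return list with \code{status}, \code{objective_value}, \code{fluxes}
#'   (named vector).
#' @export
fba_single_phase <- function(network, bound_overrides = list(),
                             objective = NULL, tol = 1e-9) {
  validate_network(network)
  lb <- network$lb; ub <- network$ub
  for (rid in names(bound_overrides)) {
    if (!rid %in% network$reaction_ids)
      stop("bound override for unknown reaction '", rid, "'")
    lb[rid] <- bound_overrides[[rid]][1]
    ub[rid] <- bound_overrides[[rid]][2]
  }
  w <- network$objective_coeffs
  if (!is.null(objective)) {
    w[] <- 0
    w[names(objective)] <- objective
  }
  res <- lp_simplex(w, network$stoich, rhs = 0, lb = lb, ub = ub,
                    maximize = TRUE, tol = tol)
  if (res$status == "failed")
    stop("LP solver failure; constraint residual: ", format(res$residual))
  list(status = res$status,
       objective_value = if (res$status == "optimal") res$objective
                         else NA_real_,
       fluxes = if (res$status == "optimal")
         stats::setNames(res$x, network$reaction_ids) else NULL)
}

#' Biomass composition at the light-to-dark transition
#'
#' Combines the functional biomass produced during the light phase with
#' the storage metabolites accumulated for the night into the biomass
#' composition at the phase transition. Functional amounts are the net
#' light-phase production of each functional-labelled species (computed
#' as \code{S \%*\% delta_c_light}); storage amounts are the transfer
#' column values.
#'
#' @param solution an optimal \code{diufba_solution}.
#' @param config the \code{diurnal_config} used (defaults to the one
#'   embedded in the solution's problem).
#' @param component_labels named character vector over carry-over species
#'   (\code{"functional"}/\code{"storage"}); defaults to the config's
#'   labels.
#' @return object of class \code{biomass_composition}: data.frame with
#'   \code{species}, \code{label}, \code{amount}, \code{fraction}
#'   (fractions sum to 1).
#' @examples
#' toy <- build_toy_model(toy_scenario())
#' sol <- solve_diufba(build_extended_problem(toy$network, toy$config))
#' transition_composition(sol)
#' @export
transition_composition <- function(solution, config = NULL,
                                   component_labels = NULL) {
  if (!identical(solution$status, "optimal"))
    stop("transition composition requires an optimal solution")
  problem <- solution$problem
  config <- config %||% problem$config
  labels <- component_labels %||% config$component_labels
  cm <- problem$col_map
  light <- names(problem$phase_durations)[1]
  light_cols <- cm$kind == "reaction" & cm$phase == light
  net_light <- as.vector(
    problem$network$stoich %*% solution$delta_c[light_cols])
  names(net_light) <- problem$network$species_ids
  amount <- vapply(names(labels), function(sp) {
    if (labels[[sp]] == "functional") net_light[[sp]]
    else unname(solution$transfers[sp])
  }, numeric(1))
  total <- sum(amount)
  if (!is.finite(total) || abs(total) < 1e-12)
    stop("transition composition undefined: total component amount is zero")
  structure(data.frame(species = names(labels),
                       label = unname(labels),
                       amount = unname(amount),
                       fraction = unname(amount) / total,
                       stringsAsFactors = FALSE),
            class = c("biomass_composition", "data.frame"))
}

#' @export
print.biomass_composition <- function(x, ...) {
  cat("Biomass composition at the light/dark transition:\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-12s %-10s %8.6g  (%.1f%%)\n", x$species[i],
                x$label[i], x$amount[i], 100 * x$fraction[i]))
  by_label <- tapply(x$fraction, x$label, sum)
  cat(sprintf("  total: %.1f%% functional / %.1f%% storage\n",
              100 * (by_label[["functional"]] %||% 0),
              100 * (by_label[["storage"]] %||% 0)))
  invisible(x)
}

#' Write a solved problem to disk
#'
#' Writes a per-column TSV (label, kind, phase, id, concentration change,
#' phase flux) and a JSON summary (status, objective, transfers, exports,
#' composition when computable).
#'
#' @param solution a \code{diufba_solution}.
#' @param path_prefix files are written as \code{<prefix>_solution.tsv}
#'   and \code{<prefix>_summary.json}.
#' @return the two paths, invisibly.
#' @export
write_solution <- function(solution, path_prefix) {
  problem <- solution$problem
  tsv <- paste0(path_prefix, "_solution.tsv")
  jsn <- paste0(path_prefix, "_summary.json")
  comp <- tryCatch(transition_composition(solution), error = function(e) NULL)
  if (identical(solution$status, "optimal")) {
    cm <- problem$col_map
    flux <- solution$delta_c
    for (ph in names(problem$phase_durations)) {
      sel <- cm$kind == "reaction" & cm$phase == ph
      flux[sel] <- flux[sel] / problem$phase_durations[[ph]]
    }
    tab <- data.frame(cm[c("label", "kind", "phase", "id")],
                      delta_c = unname(solution$delta_c),
                      phase_flux = unname(flux))
    utils::write.table(tab, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  summ <- list(status = solution$status,
               objective = solution$objective_value,
               transfers = as.list(solution$transfers),
               exports = as.list(solution$exports),
               composition = if (!is.null(comp))
                 list(species = comp$species, label = comp$label,
                      amount = comp$amount, fraction = comp$fraction,
                      percent_rounded = round(100 * comp$fraction, 1)))
  jsonlite::write_json(summ, jsn, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(c(tsv, jsn))
}
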