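#' Diurnal flux balance analysis
#'
#' The package's main entry point: replicates a metabolic network over a
#' light and a dark phase, couples the phases through transfer reactions
#' for the declared carry-over species, adds export reactions for
#' long-term accumulation, and solves the resulting linear program in one
#' shot. Because storage appears as free variables of the optimization,
#' the amount of storage metabolite laid down during the day is an
#' outcome of optimal resource management over the whole cycle rather
#' than a fixed entry of the biomass function.
#'
#' @param network a \code{\link{metabolic_network}}.
#' @param config a \code{\link{diurnal_config}} (two phases).
#' @param secondary passed to \code{\link{solve_diufba}}.
#' @return an object of class \code{diufba}: the extended problem, the
#'   LP solution, and — when the solution is optimal and carry-over
#'   species exist — the biomass composition at the light/dark
#'   transition. Methods: \code{print}, \code{summary}, \code{coef}
#'   (extended concentration-change vector), \code{plot} (transition
#'   composition).
#' @examples
#' toy <- build_toy_model(toy_scenario())
#' fit <- diufba(toy$network, toy$config)
#' fit
#' coef(fit)[c("transfer:STO", "export:BIO")]
#' @export
diufba <- function(network, config, secondary = c("none", "min_total_flux")) {
  problem <- build_extended_problem(network, config)
  solution <- solve_diufba(problem, secondary = match.arg(secondary))
  composition <- if (identical(solution$status, "optimal") &&
                     length(config$carryover_species))
    tryCatch(transition_composition(solution), error = function(e) NULL)
  structure(list(problem = problem, solution = solution,
                 composition = composition,
                 call = match.call()), class = "diufba")
}

#' @export
print.diufba <- function(x, ...) {
  cat("Diurnal flux balance analysis\n")
  cat(sprintf("  status: %s", x$solution$status))
  if (identical(x$solution$status, "optimal"))
    cat(sprintf(", objective: %.6g", x$solution$objective_value))
  cat("\n")
  if (!is.null(x$composition)) {
    by_label <- tapply(x$composition$fraction, x$composition$label, sum)
    cat(sprintf("  transition composition: %.1f%% functional / %.1f%% storage\n",
                100 * (by_label[["functional"]] %||% 0),
                100 * (by_label[["storage"]] %||% 0)))
  }
  invisible(x)
}

#' @export
summary.diufba <- function(object, ...) {
  structure(list(fit = object), class = "summary.diufba")
}

#' @export
print.summary.diufba <- function(x, ...) {
  fit <- x$fit
  print(fit)
  sol <- fit$solution
  if (identical(sol$status, "optimal")) {
    cat("\nTransfers (light -> dark):\n")
    print(sol$transfers)
    cat("\nExports:\n")
    print(sol$exports)
    for (ph in names(fit$problem$phase_durations)) {
      cat(sprintf("\nFluxes, %s phase (per hour):\n", ph))
      print(round(sol$fluxes[[ph]], 9))
    }
    if (!is.null(fit$composition)) {
      cat("\n")
      print(fit$composition)
    }
    cat(sprintf("\nMass-balance residual: %.3g\n", sol$residual))
  }
  invisible(x)
}

#' @export
coef.diufba <- function(object, ...) object$solution$delta_c

#' @export
plot.diufba <- function(x, ...) {
  if (is.null(x$composition))
    stop("nothing to plot: no transition composition available")
  comp <- x$composition
  graphics::barplot(stats::setNames(comp$fraction * 100, comp$species),
                    ylab = "share at light/dark transition [%]",
                    col = ifelse(comp$label == "functional",
                                 "forestgreen", "goldenrod"), ...)
  invisible(x)
}
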