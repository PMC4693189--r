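#' Build the transfer (transition) matrix
#'
#' One column per carry-over species, moving one unit of that species out
#' of the light-phase balance (\code{-1}) and into the dark-phase balance
#' (\code{+1}). The corresponding variables are unbounded in both
#' directions by default: transfers are reversible, so mass may also move
#' from night to day.
#'
#' @param network a \code{metabolic_network} with \code{s} species.
#' @param config a \code{diurnal_config} with \code{p} carry-over species.
#' @return sparse \code{2s x p} matrix; \code{p = 0} gives a \code{2s x 0}
#'   matrix (phases fully decoupled).
#' @export
build_transfer_matrix <- function(network, config) {
  validate_config(config, network)
  s <- length(network$species_ids)
  p <- length(config$carryover_species)
  rows <- extended_row_names(network, config)
  if (p == 0L)
    return(empty_coupling_matrix(rows))
  idx <- match(config$carryover_species, network$species_ids)
  Matrix::sparseMatrix(
    i = as.integer(c(idx, idx + s)), j = rep(seq_len(p), 2),
    x = rep(c(-1, 1), each = p), dims = c(2 * s, p),
    dimnames = list(rows,
                    paste0("transfer:", config$carryover_species)))
}

#' Build the export matrix
#'
#' One column per exportable species with a single \code{-1} entry in that
#' species' dark-phase row: exported mass accumulates beyond the diurnal
#' cycle (long-term storage or net biomass growth) and leaves the system.
#' Export variables are bounded below by zero, so accumulation can leave
#' the cycle but never enter it.
#'
#' @inheritParams build_transfer_matrix
#' @return sparse \code{2s x q} matrix.
#' @export
build_export_matrix <- function(network, config) {
  validate_config(config, network)
  s <- length(network$species_ids)
  q <- length(config$exportable_species)
  rows <- extended_row_names(network, config)
  if (q == 0L)
    return(empty_coupling_matrix(rows))
  idx <- match(config$exportable_species, network$species_ids)
  Matrix::sparseMatrix(
    i = as.integer(idx + s), j = seq_len(q), x = rep(-1, q),
    dims = c(2 * s, q),
    dimnames = list(rows,
                    paste0("export:", config$exportable_species)))
}

empty_coupling_matrix <- function(rows) {
  m <- Matrix::Matrix(0, length(rows), 0, sparse = TRUE)
  rownames(m) <- rows
  m
}

extended_row_names <- function(network, config) {
  unlist(lapply(vapply(config$phases, `[[`, character(1), "name"),
                function(ph) paste0(ph, ":", network$species_ids)))
}

#' Assemble the extended diurnal problem
#'
#' Replicates the stoichiometric matrix block-diagonally over the light
#' and dark phases and couples the blocks with transfer columns for
#' carry-over species and export columns for long-term accumulation.
#' Reaction variables are time-integrated concentration changes: the
#' phase-specific flux bounds (after overrides) are multiplied by that
#' phase's duration, so a flux bound of \code{b} over a phase of
#' \code{dt} hours becomes a concentration-change bound of \code{b * dt}.
#' Equality-constrained fluxes (\code{lb == ub}) stay equalities after
#' scaling.
#'
#' Column order is: light reactions (r), transfer (p), dark reactions
#' (r), export (q), giving \code{2r + p + q} columns over \code{2s} rows.
#'
#' @inheritParams build_transfer_matrix
#' @return an object of class \code{extended_problem} with fields
#'   \code{S_ext}, \code{v_lb_ext}, \code{v_ub_ext}, \code{w},
#'   \code{col_map} (data.frame: column, kind, phase, id, label),
#'   \code{phase_durations}, \code{network}, \code{config}.
#' @examples
#' toy <- build_toy_model(toy_scenario())
#' prob <- build_extended_problem(toy$network, toy$config)
#' dim(prob$S_ext)   # 8 x 19 for the two-phase example model
#' @export
build_extended_problem <- function(network, config) {
  validate_network(network)
  validate_config(config, network)
  if (length(config$phases) != 2L)
    stop("unsupported configuration: the validated path requires exactly ",
         "2 phases, got ", length(config$phases))
  s <- length(network$species_ids)
  r <- length(network$reaction_ids)
  p <- length(config$carryover_species)
  q <- length(config$exportable_species)
  phase_names <- vapply(config$phases, `[[`, character(1), "name")
  durations <- stats::setNames(
    vapply(config$phases, `[[`, numeric(1), "duration"), phase_names)

  Tm <- build_transfer_matrix(network, config)
  Em <- build_export_matrix(network, config)
  Z <- Matrix::Matrix(0, s, r, sparse = TRUE)
  S_ext <- cbind(rbind(network$stoich, Z), Tm, rbind(Z, network$stoich), Em)
  rownames(S_ext) <- extended_row_names(network, config)

  phase_bounds <- lapply(config$phases, function(ph) {
    lo <- network$lb; hi <- network$ub
    for (rid in names(ph$bounds)) {
      lo[rid] <- ph$bounds[[rid]][1]
      hi[rid] <- ph$bounds[[rid]][2]
    }
    list(lb = lo * ph$duration, ub = hi * ph$duration)
  })
  tb <- vapply(config$carryover_species, function(sp) {
    b <- config$transfer_bounds[[sp]]
    if (is.null(b)) c(-Inf, Inf) else as.numeric(b)
  }, numeric(2))
  lb <- c(phase_bounds[[1]]$lb, if (p) tb[1, ] else numeric(0),
          phase_bounds[[2]]$lb, numeric(q))
  ub <- c(phase_bounds[[1]]$ub, if (p) tb[2, ] else numeric(0),
          phase_bounds[[2]]$ub, rep(Inf, q))

  col_map <- data.frame(
    column = seq_len(2 * r + p + q),
    kind = c(rep("reaction", r), rep("transfer", p),
             rep("reaction", r), rep("export", q)),
    phase = c(rep(phase_names[1], r), rep(NA_character_, p),
              rep(phase_names[2], r), rep(NA_character_, q)),
    id = c(network$reaction_ids, config$carryover_species,
           network$reaction_ids, config$exportable_species),
    stringsAsFactors = FALSE)
  col_map$label <- ifelse(col_map$kind == "reaction",
                          paste0(col_map$phase, ":", col_map$id),
                          paste0(col_map$kind, ":", col_map$id))
  colnames(S_ext) <- col_map$label

  w <- stats::setNames(numeric(nrow(col_map)), col_map$label)
  if (length(config$objective)) {
    unknown <- setdiff(names(config$objective), col_map$label)
    if (length(unknown))
      stop("objective refers to unknown column(s): ",
           paste(unknown, collapse = ", "))
    w[names(config$objective)] <- config$objective
  } else if (q > 0) {
    w[col_map$kind == "export"] <- 1
  } else {
    ## no exports declared: fall back on the base model objective per phase
    w[col_map$kind == "reaction"] <-
      rep(network$objective_coeffs, 2)
  }

  structure(list(S_ext = S_ext, v_lb_ext = unname(lb),
                 v_ub_ext = unname(ub), w = w, col_map = col_map,
                 phase_durations = durations,
                 network = network, config = config),
            class = "extended_problem")
}

#' @export
print.extended_problem <- function(x, ...) {
  km <- table(x$col_map$kind)
  cat(sprintf("Extended diurnal problem: %d rows x %d columns\n",
              nrow(x$S_ext), ncol(x$S_ext)))
  cat(sprintf("  reaction columns: %d, transfer: %d, export: %d\n",
              km[["reaction"]],
              if ("transfer" %in% names(km)) km[["transfer"]] else 0L,
              if ("export" %in% names(km)) km[["export"]] else 0L))
  cat("  phases:", paste(sprintf("%s (%g h)", names(x$phase_durations),
                                 x$phase_durations), collapse = ", "), "\n")
  invisible(x)
}

## resolve a column label like "light:EX_sub", "transfer:STO",
## "export:BIO" to a column index
resolve_column <- function(problem, var) {
  hit <- match(var, problem$col_map$label)
  if (is.na(hit))
    stop("unknown extended-problem variable '", var, "'")
  hit
}

#' Recover per-phase fluxes from a solution vector
#'
#' Reaction-block entries of the extended solution are concentration
#' changes; dividing by the phase duration recovers the phase fluxes that
#' a classical FBA would report. Transfer and export entries are amounts,
#' not rates, and are returned unscaled.
#'
#' @param solution_vector extended vector (length \code{2r + p + q}).
#' @param problem the \code{extended_problem} it solves.
#' @return list with one named flux vector per phase plus \code{transfers}
#'   and \code{exports} (amounts).
#' @export
phase_fluxes <- function(solution_vector, problem) {
  if (length(solution_vector) != nrow(problem$col_map))
    stop("solution vector length ", length(solution_vector),
         " does not match problem columns ", nrow(problem$col_map))
  cm <- problem$col_map
  out <- lapply(names(problem$phase_durations), function(ph) {
    sel <- cm$kind == "reaction" & cm$phase == ph
    stats::setNames(solution_vector[sel] / problem$phase_durations[[ph]],
                    cm$id[sel])
  })
  names(out) <- names(problem$phase_durations)
  out$transfers <- stats::setNames(
    solution_vector[cm$kind == "transfer"], cm$id[cm$kind == "transfer"])
  out$exports <- stats::setNames(
    solution_vector[cm$kind == "export"], cm$id[cm$kind == "export"])
  out
}

#' Serialize an extended problem for external inspection
#'
#' Writes the extended stoichiometric matrix in MatrixMarket format plus a
#' TSV column map (column index, kind, phase, id, bounds, objective
#' weight), e.g. for debugging against an external LP solver.
#'
#' @param problem an \code{extended_problem}.
#' @param path_prefix files are written as \code{<prefix>.mtx} and
#'   \code{<prefix>_columns.tsv}.
#' @return the two paths, invisibly.
#' @export
write_extended_problem <- function(problem, path_prefix) {
  mtx <- paste0(path_prefix, ".mtx")
  Matrix::writeMM(problem$S_ext, mtx)
  tab <- problem$col_map
  tab$lb <- num_fmt(problem$v_lb_ext)
  tab$ub <- num_fmt(problem$v_ub_ext)
  tab$objective_weight <- num_fmt(problem$w)
  tsv <- paste0(path_prefix, "_columns.tsv")
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(mtx, tsv))
}
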