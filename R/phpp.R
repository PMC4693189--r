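#' Diurnal phenotypic phase plane scan
#'
#' Fixes one or two extended-problem variables on a grid of values and
#' re-solves the diurnal LP for every combination, recording the
#' constrained optimum. Scanned variables may be any extended column —
#' a reaction in either phase, a transfer amount, or an export amount —
#' addressed by their column label (\code{"light:EX_sub"},
#' \code{"transfer:STO"}, \code{"export:BIO"}, ...). Variables are fixed
#' by equality (\code{lb = ub = value}); infeasible cells are masked, not
#' skipped, so the grid shape is stable.
#'
#' @param problem an \code{\link{build_extended_problem}} result.
#' @param var1 column label of the first scanned variable.
#' @param range1 numeric \code{c(lo, hi, m)}: \code{m} equally spaced
#'   values from \code{lo} to \code{hi} (in the variable's native units,
#'   i.e. concentration changes/amounts).
#' @param var2,range2 optional second axis; omit for a one-dimensional
#'   scan.
#' @param tol LP tolerance.
#' @return object of class \code{phpp_grid}: \code{axis1}, \code{axis2},
#'   \code{objective} (m x n matrix), \code{feasible} (mask),
#'   \code{var1}, \code{var2}.
#' @examples
#' toy <- build_toy_model(toy_scenario())
#' prob <- build_extended_problem(toy$network, toy$config)
#' g <- phpp_scan(prob, "transfer:STO", c(0, 0.125, 6))
#' g$objective[, 1]   # 0.7 + 0.6 * t along the scan
#' @export
phpp_scan <- function(problem, var1, range1, var2 = NULL, range2 = NULL,
                      tol = 1e-9) {
  stopifnot(inherits(problem, "extended_problem"))
  axis1 <- expand_range(range1)
  j1 <- resolve_column(problem, var1)
  if (!is.null(var2)) {
    axis2 <- expand_range(range2)
    j2 <- resolve_column(problem, var2)
  } else {
    axis2 <- NA_real_
    j2 <- NULL
  }
  m <- length(axis1); n <- length(axis2)
  objective <- matrix(NA_real_, m, n)
  feasible <- matrix(FALSE, m, n)
  for (j in seq_len(n)) {          # column-major: axis1 varies fastest
    for (i in seq_len(m)) {
      lb <- problem$v_lb_ext; ub <- problem$v_ub_ext
      # a fixed value outside the variable's hard bounds is infeasible
      if (axis1[i] < lb[j1] - tol || axis1[i] > ub[j1] + tol) next
      lb[j1] <- ub[j1] <- axis1[i]
      if (!is.null(j2)) {
        if (axis2[j] < lb[j2] - tol || axis2[j] > ub[j2] + tol) next
        lb[j2] <- ub[j2] <- axis2[j]
      }
      res <- lp_simplex(problem$w, problem$S_ext, rhs = 0,
                        lb = lb, ub = ub, maximize = TRUE,
                        tol = tol)
      if (res$status == "optimal") {
        objective[i, j] <- res$objective
        feasible[i, j] <- TRUE
      }
    }
  }
  structure(list(var1 = var1, var2 = var2, axis1 = axis1, axis2 = axis2,
                 objective = objective, feasible = feasible,
                 problem = problem),
            class = "phpp_grid")
}

expand_range <- function(rg) {
  rg <- as.numeric(rg)
  if (length(rg) != 3L)
    stop("a scan range must be c(lo, hi, n)")
  if (rg[1] > rg[2]) stop("degenerate scan range: lo > hi")
  n <- as.integer(rg[3])
  if (n < 1L) stop("a scan range needs at least one point")
  if (n == 1L) return(rg[1])
  seq(rg[1], rg[2], length.out = n)
}

#' @export
print.phpp_grid <- function(x, ...) {
  cat(sprintf("Phenotypic phase plane: %s (%d values)", x$var1,
              length(x$axis1)))
  if (!is.null(x$var2))
    cat(sprintf(" x %s (%d values)", x$var2, length(x$axis2)))
  cat("\n")
  cat(sprintf("  feasible cells: %d / %d; max objective: %.6g\n",
              sum(x$feasible), length(x$feasible),
              suppressWarnings(max(x$objective, na.rm = TRUE))))
  invisible(x)
}

#' Classify metabolic modes on a phase plane
#'
#' Labels contiguous regions of constant objective gradient. The LP value
#' function is piecewise linear in the fixed variable values, so each
#' linear piece — a metabolic mode, i.e. one active flux routing — shows
#' up as a region of constant finite-difference gradient. Gradients are
#' compared at a tolerance; 4-neighbour connected cells with equal
#' gradient share a mode id (numbered in column-major discovery order).
#'
#' @param grid a solved \code{\link{phpp_scan}} grid.
#' @param tol gradient comparison tolerance.
#' @return object of class \code{phpp_modes}: \code{modes} (integer
#'   matrix, \code{NA} on infeasible cells), \code{n_modes},
#'   \code{gradients} (data.frame of per-mode gradient components).
#' @export
classify_modes <- function(grid, tol = 1e-6) {
  stopifnot(inherits(grid, "phpp_grid"))
  obj <- grid$objective
  m <- nrow(obj); n <- ncol(obj)
  if (max(m, n) < 3L) {
    warning("grid too small for mode classification; ",
            "returning a single region")
    modes <- matrix(ifelse(grid$feasible, 1L, NA_integer_), m, n)
    return(structure(list(modes = modes, n_modes = 1L,
                          gradients = NULL), class = "phpp_modes"))
  }
  fd <- function(vals, axis, along_rows) {
    g <- matrix(0, m, n)
    if ((if (along_rows) m else n) < 2L) return(g)
    if (along_rows) {
      for (i in seq_len(m)) {
        k <- if (i < m) i else i - 1L
        g[i, ] <- (vals[k + 1L, ] - vals[k, ]) / (axis[k + 1L] - axis[k])
      }
    } else {
      for (j in seq_len(n)) {
        k <- if (j < n) j else j - 1L
        g[, j] <- (vals[, k + 1L] - vals[, k]) / (axis[k + 1L] - axis[k])
      }
    }
    g
  }
  g1 <- fd(obj, grid$axis1, TRUE)
  g2 <- fd(obj, grid$axis2, FALSE)
  key <- matrix(paste(round(g1 / tol), round(g2 / tol)), m, n)
  key[!grid$feasible | is.na(g1) | is.na(g2)] <- NA
  modes <- matrix(NA_integer_, m, n)
  nxt <- 0L
  grads <- list()
  for (j in seq_len(n)) for (i in seq_len(m)) {
    if (is.na(key[i, j]) || !is.na(modes[i, j])) next
    nxt <- nxt + 1L
    ## flood fill over the 4-neighbourhood
    stack <- list(c(i, j))
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      ci <- cur[1]; cj <- cur[2]
      if (is.na(key[ci, cj]) || !is.na(modes[ci, cj]) ||
          key[ci, cj] != key[i, j]) next
      modes[ci, cj] <- nxt
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ni <- ci + d[1]; nj <- cj + d[2]
        if (ni >= 1 && ni <= m && nj >= 1 && nj <= n &&
            is.na(modes[ni, nj]))
          stack[[length(stack) + 1L]] <- c(ni, nj)
      }
    }
    grads[[nxt]] <- c(g1[i, j], g2[i, j])
  }
  structure(list(
    modes = modes, n_modes = nxt,
    gradients = if (nxt) data.frame(
      mode = seq_len(nxt),
      grad1 = vapply(grads, `[`, numeric(1), 1),
      grad2 = vapply(grads, `[`, numeric(1), 2))),
    class = "phpp_modes")
}

#' @export
print.phpp_modes <- function(x, ...) {
  cat(sprintf("Metabolic mode map: %d region(s)\n", x$n_modes))
  if (!is.null(x$gradients)) print(x$gradients, row.names = FALSE)
  invisible(x)
}

#' Heat map of a phenotypic phase plane
#'
#' @param x a \code{phpp_grid}.
#' @param ... forwarded to \code{graphics::image}.
#' @export
plot.phpp_grid <- function(x, ...) {
  if (is.null(x$var2)) {
    graphics::plot(x$axis1, x$objective[, 1], type = "b",
                   xlab = x$var1, ylab = "objective", ...)
  } else {
    graphics::image(x$axis1, x$axis2, x$objective,
                    xlab = x$var1, ylab = x$var2,
                    col = grDevices::hcl.colors(64, "viridis"), ...)
    graphics::contour(x$axis1, x$axis2, x$objective, add = TRUE,
                      col = "white")
  }
  invisible(x)
}

#' Export a phase plane grid as long-format CSV
#'
#' Columns: \code{axis1}, \code{axis2}, \code{objective},
#' \code{feasible}, and \code{mode} when a classification is supplied.
#'
#' @param grid a \code{phpp_grid}.
#' @param path output CSV path.
#' @param modes optional \code{\link{classify_modes}} result.
#' @return \code{path}, invisibly.
#' @export
write_phpp <- function(grid, path, modes = NULL) {
  m <- length(grid$axis1); n <- length(grid$axis2)
  tab <- data.frame(
    axis1 = rep(grid$axis1, n),
    axis2 = rep(grid$axis2, each = m),
    objective = as.vector(grid$objective),
    feasible = as.vector(grid$feasible))
  if (!is.null(modes)) tab$mode <- as.vector(modes$modes)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
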