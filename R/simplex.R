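#' Bounded-variable simplex linear-programming solver
#'
#' Solves \code{max/min obj' x} subject to \code{A x = rhs} and
#' \code{lb <= x <= ub} with a dense two-phase primal simplex using Bland's
#' anti-cycling rule. Variables may be fixed (\code{lb == ub}), free
#' (\code{-Inf, Inf}) or bounded on either side.
#'
#' This is the LP engine behind every flux balance computation in the
#' package. It is written for the moderate problem sizes of extended
#' diurnal models (hundreds to a few thousand columns); the basis inverse
#' is recomputed by dense factorization at every pivot, trading speed for
#' numerical transparency.
#'
#' @param obj numeric objective vector (length n).
#' @param A constraint matrix (m x n), dense or \code{Matrix} sparse.
#' @param rhs right-hand side (length m, recycled scalar allowed).
#' @param lb,ub variable bounds (length n, recycled; \code{-Inf}/\code{Inf}
#'   allowed).
#' @param maximize logical; maximize (default) or minimize.
#' @param tol feasibility/optimality tolerance on the scale of the data.
#' @param max_iter pivot cap; default \code{200 * (n + m) + 2000}.
#' @return list with elements \code{status} (one of \code{"optimal"},
#'   \code{"infeasible"}, \code{"unbounded"}, \code{"failed"}), \code{x}
#'   (solution, \code{NA} unless optimal), \code{objective}, \code{iter},
#'   and \code{residual} (max-norm of \code{A x - rhs} at the solution).
#' @examples
#' # a three-step chain: throughput limited by the tightest bound
#' A <- rbind(c(1, -1, 0), c(0, 1, -1))
#' lp_simplex(c(0, 0, 1), A, lb = 0, ub = c(2, 0.75, 5))$objective
#' @export
lp_simplex <- function(obj, A, rhs = 0, lb = -Inf, ub = Inf,
                       maximize = TRUE, tol = 1e-9, max_iter = NULL) {
  A <- as.matrix(A)
  storage.mode(A) <- "double"
  m <- nrow(A)
  n <- ncol(A)
  if (length(obj) != n) stop("objective length does not match ncol(A)")
  rhs <- rep_len(as.numeric(rhs), m)
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  if (any(lb > ub)) stop("lb > ub for variable(s) ",
                         paste(which(lb > ub), collapse = ", "))
  if (is.null(max_iter)) max_iter <- 200L * (n + m) + 2000L
  cost <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  ## scale tolerance with problem data
  scale <- max(1, max(abs(A)), max(abs(rhs)))
  ftol <- tol * scale

  ## initial nonbasic point: finite bound if available, free vars at 0
  x <- numeric(n)
  vstat <- character(n)              # "lb", "ub", "free"
  for (j in seq_len(n)) {
    if (is.finite(lb[j])) { x[j] <- lb[j]; vstat[j] <- "lb" }
    else if (is.finite(ub[j])) { x[j] <- ub[j]; vstat[j] <- "ub" }
    else { x[j] <- 0; vstat[j] <- "free" }
  }

  ## artificial columns: identity with signs matching the initial residual
  resid0 <- rhs - as.vector(A %*% x)
  sgn <- ifelse(resid0 >= 0, 1, -1)
  Aa <- cbind(A, diag(sgn, nrow = m, ncol = m))
  ntot <- n + m
  lbx <- c(lb, numeric(m))
  ubx <- c(ub, rep(Inf, m))
  x <- c(x, abs(resid0))
  vstat <- c(vstat, rep("basic", m))
  basis <- n + seq_len(m)

  run_phase <- function(cvec, basis, x, vstat, iter0) {
    iter <- iter0
    repeat {
      if (iter > max_iter)
        return(list(code = "failed", basis = basis, x = x, vstat = vstat,
                    iter = iter))
      B <- Aa[, basis, drop = FALSE]
      nonbasic <- setdiff(seq_len(ntot), basis)
      xn <- x[nonbasic]
      bred <- rhs - if (length(nonbasic))
        as.vector(Aa[, nonbasic, drop = FALSE] %*% xn) else numeric(m)
      xb <- tryCatch(solve(B, bred), error = function(e) NULL)
      if (is.null(xb))
        return(list(code = "failed", basis = basis, x = x, vstat = vstat,
                    iter = iter))
      x[basis] <- xb
      y <- tryCatch(solve(t(B), cvec[basis]), error = function(e) NULL)
      if (is.null(y))
        return(list(code = "failed", basis = basis, x = x, vstat = vstat,
                    iter = iter))
      ## reduced costs of nonbasic variables
      d <- cvec[nonbasic] - as.vector(crossprod(Aa[, nonbasic, drop = FALSE], y))
      span <- ubx[nonbasic] - lbx[nonbasic]
      dirs <- numeric(length(nonbasic))
      elig <- (vstat[nonbasic] == "lb" & d < -ftol) |
              (vstat[nonbasic] == "free" & abs(d) > ftol) |
              (vstat[nonbasic] == "ub" & d > ftol)
      elig <- elig & span > 0
      if (!any(elig))
        return(list(code = "optimal", basis = basis, x = x, vstat = vstat,
                    iter = iter))
      ## Bland: smallest variable index among eligible
      cand <- nonbasic[elig]
      jpos <- which(elig)[which.min(cand)]
      j <- nonbasic[jpos]
      dir <- if (vstat[j] == "ub") -1 else if (vstat[j] == "free")
        -sign(d[jpos]) else 1
      delta <- solve(B, Aa[, j])
      ## ratio test: basic variables hitting a bound, or the entering
      ## variable traversing its own span
      rate <- -dir * delta
      ratio <- rep(Inf, m)
      hit <- character(m)
      for (i in seq_len(m)) {
        bi <- basis[i]
        if (rate[i] > ftol) {
          ratio[i] <- (ubx[bi] - x[bi]) / rate[i]
          hit[i] <- "ub"
        } else if (rate[i] < -ftol) {
          ratio[i] <- (x[bi] - lbx[bi]) / (-rate[i])
          hit[i] <- "lb"
        }
      }
      ratio <- pmax(ratio, 0)
      own <- if (is.finite(span[jpos])) span[jpos] else Inf
      tmax <- min(own, ratio)
      if (!is.finite(tmax))
        return(list(code = "unbounded", basis = basis, x = x, vstat = vstat,
                    iter = iter))
      x[j] <- x[j] + dir * tmax
      x[basis] <- x[basis] - dir * tmax * delta
      if (own <= tmax + ftol && own <= min(ratio) + ftol) {
        ## bound flip: entering variable traverses its own span
        vstat[j] <- if (vstat[j] == "lb") "ub" else "lb"
        x[j] <- if (vstat[j] == "lb") lbx[j] else ubx[j]
      } else {
        ## Bland tie-break on the leaving variable: smallest index
        near <- which(ratio <= tmax + ftol)
        leave_pos <- near[which.min(basis[near])]
        lv <- basis[leave_pos]
        vstat[lv] <- hit[leave_pos]
        x[lv] <- if (hit[leave_pos] == "lb") lbx[lv] else ubx[lv]
        basis[leave_pos] <- j
        vstat[j] <- "basic"
      }
      iter <- iter + 1L
    }
  }

  ## phase 1: drive artificials to zero
  c1 <- c(numeric(n), rep(1, m))
  p1 <- run_phase(c1, basis, x, vstat, 0L)
  if (p1$code == "failed")
    return(list(status = "failed", x = rep(NA_real_, n), objective = NA_real_,
                iter = p1$iter, residual = NA_real_))
  if (p1$code == "unbounded")
    return(list(status = "failed", x = rep(NA_real_, n), objective = NA_real_,
                iter = p1$iter, residual = NA_real_))
  art_sum <- sum(p1$x[n + seq_len(m)])
  if (art_sum > 1e3 * ftol)
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objective = NA_real_, iter = p1$iter, residual = art_sum))

  ## phase 2: clamp artificials at zero, optimize the true objective
  ubx[n + seq_len(m)] <- 0
  x <- p1$x
  x[n + seq_len(m)][p1$vstat[n + seq_len(m)] != "basic"] <- 0
  c2 <- c(cost, numeric(m))
  p2 <- run_phase(c2, p1$basis, x, p1$vstat, p1$iter)
  if (p2$code == "failed")
    return(list(status = "failed", x = rep(NA_real_, n), objective = NA_real_,
                iter = p2$iter, residual = NA_real_))
  if (p2$code == "unbounded")
    return(list(status = "unbounded", x = rep(NA_real_, n),
                objective = if (maximize) Inf else -Inf, iter = p2$iter,
                residual = NA_real_))
  sol <- p2$x[seq_len(n)]
  ## snap solved values onto their bounds within tolerance
  sol <- pmin(pmax(sol, lb), ub)
  res <- max(abs(as.vector(A %*% sol) - rhs))
  list(status = "optimal", x = sol,
       objective = sum(obj * sol), iter = p2$iter, residual = res)
}
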