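#' Construct a metabolic network
#'
#' The canonical in-memory representation of a stoichiometric model: a
#' sparse species-by-reaction matrix \code{S} with per-reaction flux bounds
#' and objective coefficients. Coefficient signs follow the usual
#' convention: consumed species negative, produced species positive.
#' Reversibility is encoded purely by the sign of the lower bound.
#'
#' @param stoich species x reactions matrix (coercible to
#'   \code{Matrix::sparseMatrix}) with unique row and column names.
#' @param lb,ub per-reaction flux bounds (mmol/gDCW/h, or M/h for the
#'   example model); recycled scalars allowed.
#' @param objective per-reaction objective coefficients, default all zero.
#' @param species_meta optional data.frame with columns \code{id},
#'   \code{name}, \code{compartment}; defaults are generated.
#' @return an object of class \code{metabolic_network} with fields
#'   \code{species_ids}, \code{reaction_ids}, \code{stoich}, \code{lb},
#'   \code{ub}, \code{objective_coeffs}, \code{species_meta}.
#' @examples
#' S <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 1), x = c(-1, 1),
#'                           dimnames = list(c("A", "B"), "v1"))
#' net <- metabolic_network(S, lb = 0, ub = 10)
#' net
#' @export
metabolic_network <- function(stoich, lb, ub, objective = 0,
                              species_meta = NULL) {
  stoich <- methods::as(methods::as(Matrix::Matrix(stoich, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(stoich)) || is.null(colnames(stoich)))
    stop("stoich must carry species (row) and reaction (column) names")
  r <- ncol(stoich)
  net <- structure(list(
    species_ids = rownames(stoich),
    reaction_ids = colnames(stoich),
    stoich = stoich,
    lb = stats::setNames(rep_len(as.numeric(lb), r), colnames(stoich)),
    ub = stats::setNames(rep_len(as.numeric(ub), r), colnames(stoich)),
    objective_coeffs = stats::setNames(rep_len(as.numeric(objective), r),
                                       colnames(stoich)),
    species_meta = species_meta
  ), class = "metabolic_network")
  if (is.null(species_meta))
    net$species_meta <- data.frame(id = net$species_ids,
                                   name = net$species_ids,
                                   compartment = "c",
                                   stringsAsFactors = FALSE)
  validate_network(net)
}

#' Validate a metabolic network
#'
#' Checks the structural invariants of a \code{metabolic_network}:
#' matching dimensions, unique identifiers, \code{lb <= ub}, and no
#' silently empty reaction columns.
#'
#' @param net a \code{metabolic_network}.
#' @param allow_empty_columns keep all-zero reaction columns (placeholder
#'   exchanges) without erroring.
#' @return the validated network, invisibly unchanged.
#' @export
validate_network <- function(net, allow_empty_columns = TRUE) {
  if (!inherits(net, "metabolic_network")) stop("not a metabolic_network")
  if (is.null(net$stoich)) stop("empty network: no stoich matrix")
  s <- length(net$species_ids); r <- length(net$reaction_ids)
  if (nrow(net$stoich) != s || ncol(net$stoich) != r)
    stop("stoich dimensions do not match identifier lists")
  if (anyDuplicated(net$species_ids))
    stop("duplicate species identifier: ",
         net$species_ids[duplicated(net$species_ids)][1])
  if (anyDuplicated(net$reaction_ids))
    stop("duplicate reaction identifier: ",
         net$reaction_ids[duplicated(net$reaction_ids)][1])
  if (length(net$lb) != r || length(net$ub) != r)
    stop("bound vectors must have one entry per reaction")
  bad <- which(net$lb > net$ub)
  if (length(bad))
    stop("lb > ub for reaction ", net$reaction_ids[bad[1]])
  if (!allow_empty_columns) {
    nz <- Matrix::colSums(net$stoich != 0)
    if (any(nz == 0))
      stop("all-zero stoichiometry column: ",
           net$reaction_ids[which(nz == 0)[1]])
  }
  invisible(net)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("Metabolic network: %d species x %d reactions\n",
              length(x$species_ids), length(x$reaction_ids)))
  nrev <- sum(x$lb < 0)
  cat(sprintf("  reversible reactions: %d; nonzero objective: %d\n",
              nrev, sum(x$objective_coeffs != 0)))
  cat("  compartments:",
      paste(unique(x$species_meta$compartment), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.metabolic_network <- function(x) dim(x$stoich)

## internal: append columns (exchange/demand style) to a network copy.
## cols is a named list: id -> list(stoich = named numeric, lb, ub, obj)
network_add_columns <- function(net, cols) {
  s <- length(net$species_ids)
  add <- Matrix::Matrix(0, s, length(cols), sparse = TRUE,
                        dimnames = list(net$species_ids, names(cols)))
  lb2 <- ub2 <- obj2 <- numeric(length(cols))
  for (k in seq_along(cols)) {
    cc <- cols[[k]]
    add[names(cc$stoich), k] <- cc$stoich
    lb2[k] <- cc$lb; ub2[k] <- cc$ub
    obj2[k] <- if (is.null(cc$obj)) 0 else cc$obj
  }
  metabolic_network(cbind(net$stoich, add),
                    lb = c(net$lb, lb2), ub = c(net$ub, ub2),
                    objective = c(net$objective_coeffs, obj2),
                    species_meta = net$species_meta)
}
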