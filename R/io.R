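#' Read a stoichiometric model
#'
#' Reads a metabolic model from SBML Level 3 with the FBC v2 package, a
#' COBRA-style JSON file, or the package's plain TSV reaction-table
#' dialect, and returns a validated \code{\link{metabolic_network}}.
#' Species and reaction order is preserved exactly as read; every matrix
#' index in the package refers to these orders.
#'
#' The TSV dialect has columns \code{reaction_id}, \code{equation},
#' \code{lb}, \code{ub}, \code{objective}. Equations use \code{" + "} to
#' separate terms, \code{"->"} for irreversible and \code{"<=>"} for
#' reversible reactions, with an optional numeric coefficient prefix
#' (default 1); an empty side denotes an exchange with the environment,
#' e.g. \code{"-> SUB"} for a supply.
#'
#' @param path file path.
#' @param format one of \code{"auto"} (by extension), \code{"tsv"},
#'   \code{"json"}, \code{"sbml"}.
#' @return a \code{metabolic_network}.
#' @seealso \code{\link{write_model}}
#' @export
read_model <- function(path, format = c("auto", "tsv", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "auto") format <- guess_format(path)
  switch(format,
         tsv = read_model_tsv(path),
         json = read_model_json(path),
         sbml = read_model_sbml(path))
}

#' Write a stoichiometric model
#'
#' Serializes a \code{metabolic_network} so that \code{\link{read_model}}
#' reproduces the stoichiometry, bounds, identifiers and their order
#' exactly. Numeric values are written with 15 significant digits so that
#' rational-looking coefficients survive the round trip.
#'
#' @param network a validated \code{metabolic_network}.
#' @param path output file path.
#' @param format as in \code{\link{read_model}} (\code{"auto"} = by
#'   extension of \code{path}).
#' @return \code{path}, invisibly.
#' @export
write_model <- function(network, path,
                        format = c("auto", "tsv", "json", "sbml")) {
  format <- match.arg(format)
  validate_network(network)
  if (length(network$reaction_ids) == 0L || length(network$species_ids) == 0L)
    stop("refusing to write an empty network")
  if (format == "auto") format <- guess_format(path)
  switch(format,
         tsv = write_model_tsv(network, path),
         json = write_model_json(network, path),
         sbml = write_model_sbml(network, path))
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tsv = "tsv", txt = "tsv",
         json = "json",
         xml = "sbml", sbml = "sbml",
         stop("cannot guess model format from extension '.", ext, "'"))
}

num_fmt <- function(x) {
  out <- vapply(x, function(v) {
    if (!is.finite(v)) {
      if (is.na(v)) "NA" else if (v > 0) "Inf" else "-Inf"
    } else sprintf("%.15g", v)
  }, character(1))
  out
}

## ---- TSV dialect -----------------------------------------------------

parse_equation <- function(eq, reaction_id) {
  rev_arrow <- grepl("<=>", eq, fixed = TRUE)
  sides <- if (rev_arrow) strsplit(eq, "<=>", fixed = TRUE)[[1]]
           else strsplit(eq, "->", fixed = TRUE)[[1]]
  if (!grepl("->|<=>", eq))
    stop("equation for '", reaction_id, "' lacks an arrow ('->' or '<=>')")
  if (length(sides) == 1L) sides <- c(sides, "")
  if (length(sides) != 2L)
    stop("equation for '", reaction_id, "' has more than one arrow")
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (txt == "") return(stats::setNames(numeric(0), character(0)))
    terms <- trimws(strsplit(txt, " + ", fixed = TRUE)[[1]])
    coef <- numeric(length(terms)); sp <- character(length(terms))
    for (k in seq_along(terms)) {
      mm <- regmatches(terms[k],
        regexec("^(?:([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)\\s+)?(\\S+)$",
                terms[k]))[[1]]
      if (length(mm) == 0L)
        stop("cannot parse term '", terms[k], "' in reaction '",
             reaction_id, "'")
      coef[k] <- if (mm[2] == "") 1 else as.numeric(mm[2])
      sp[k] <- mm[3]
    }
    stats::setNames(sign * coef, sp)
  }
  c(parse_side(sides[1], -1), parse_side(sides[2], +1))
}

read_model_tsv <- function(path) {
  tab <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) stop("TSV parse failure in ", path, ": ",
                             conditionMessage(e)))
  need <- c("reaction_id", "equation", "lb", "ub")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("TSV model lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(tab$objective)) tab$objective <- 0
  terms <- lapply(seq_len(nrow(tab)), function(i) {
    tt <- parse_equation(tab$equation[i], tab$reaction_id[i])
    ## merge duplicated species within one equation (e.g. A -> A + B)
    if (anyDuplicated(names(tt)))
      tt <- vapply(split(tt, names(tt)), sum, numeric(1))
    tt
  })
  species <- unique(unlist(lapply(terms, names)))
  if (length(species) == 0L) stop("model defines no species")
  ii <- unlist(lapply(terms, function(tt) match(names(tt), species)))
  jj <- rep(seq_along(terms), lengths(terms))
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = unlist(terms),
                            dims = c(length(species), nrow(tab)),
                            dimnames = list(species, tab$reaction_id))
  metabolic_network(S, lb = as.numeric(tab$lb), ub = as.numeric(tab$ub),
                    objective = as.numeric(tab$objective))
}

format_equation <- function(net, j) {
  col <- net$stoich[, j]
  lhs <- which(col < 0); rhs <- which(col > 0)
  term <- function(idx) {
    coef <- abs(col[idx])
    paste(ifelse(coef == 1, net$species_ids[idx],
                 paste(num_fmt(coef), net$species_ids[idx])),
          collapse = " + ")
  }
  arrow <- if (net$lb[j] < 0) "<=>" else "->"
  paste(term(lhs), arrow, term(rhs))
}

write_model_tsv <- function(net, path) {
  eqs <- vapply(seq_along(net$reaction_ids),
                function(j) format_equation(net, j), character(1))
  tab <- data.frame(reaction_id = net$reaction_ids, equation = eqs,
                    lb = num_fmt(net$lb), ub = num_fmt(net$ub),
                    objective = num_fmt(net$objective_coeffs),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

## ---- COBRA-style JSON ------------------------------------------------

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("JSON parse failure in ", path,
                                           ": ", conditionMessage(e)))
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("JSON model lacks 'metabolites' or 'reactions'")
  species <- vapply(doc$metabolites, function(mm) mm$id, character(1))
  meta <- data.frame(
    id = species,
    name = vapply(doc$metabolites,
                  function(mm) mm$name %||% mm$id, character(1)),
    compartment = vapply(doc$metabolites,
                         function(mm) mm$compartment %||% "c", character(1)),
    stringsAsFactors = FALSE)
  rxn_ids <- vapply(doc$reactions, function(rr) rr$id, character(1))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(doc$reactions)) {
    mets <- doc$reactions[[j]]$metabolites
    if (length(mets)) {
      idx <- match(names(mets), species)
      if (anyNA(idx))
        stop("reaction '", rxn_ids[j], "' references unknown species ",
             names(mets)[is.na(idx)][1])
      ii <- c(ii, idx); jj <- c(jj, rep(j, length(mets)))
      xx <- c(xx, as.numeric(unlist(mets)))
    }
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(species), length(rxn_ids)),
                            dimnames = list(species, rxn_ids))
  js_num <- function(v, default) {
    if (is.null(v)) return(default)
    if (identical(v, "inf") || identical(v, "Infinity")) return(Inf)
    if (identical(v, "-inf") || identical(v, "-Infinity")) return(-Inf)
    as.numeric(v)
  }
  metabolic_network(
    S,
    lb = vapply(doc$reactions, function(rr) js_num(rr$lower_bound, -Inf),
                numeric(1)),
    ub = vapply(doc$reactions, function(rr) js_num(rr$upper_bound, Inf),
                numeric(1)),
    objective = vapply(doc$reactions,
                       function(rr) js_num(rr$objective_coefficient, 0),
                       numeric(1)),
    species_meta = meta)
}

write_model_json <- function(net, path) {
  mets <- lapply(seq_along(net$species_ids), function(i) list(
    id = net$species_ids[i],
    name = net$species_meta$name[i],
    compartment = net$species_meta$compartment[i]))
  rxns <- lapply(seq_along(net$reaction_ids), function(j) {
    col <- net$stoich[, j]
    nz <- which(col != 0)
    list(id = net$reaction_ids[j],
         metabolites = as.list(stats::setNames(col[nz],
                                               net$species_ids[nz])),
         lower_bound = unbox_inf(net$lb[j]),
         upper_bound = unbox_inf(net$ub[j]),
         objective_coefficient = unname(net$objective_coeffs[j]))
  })
  jsonlite::write_json(list(metabolites = mets, reactions = rxns), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

unbox_inf <- function(v) {
  v <- unname(v)
  if (!is.finite(v)) (if (v > 0) "inf" else "-inf") else v
}

`%||%` <- function(a, b) if (is.null(a)) b else a
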