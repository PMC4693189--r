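## SBML Level 3 Version 1 + FBC v2 reader/writer.
##
## Covers the subset needed for constraint-based models: species with
## compartment tags, reactions with stoichiometry, flux bounds referenced
## through global parameters, and the active (maximization) objective.
## GPR rules, units and annotations are ignored on read and not written.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

xml_esc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

sbml_num <- function(v) {
  if (!is.finite(v)) (if (v > 0) "INF" else "-INF") else sprintf("%.15g", v)
}

write_model_sbml <- function(net, path) {
  comps <- unique(net$species_meta$compartment)
  ## one shared parameter per distinct bound value
  vals <- unique(c(net$lb, net$ub))
  pid <- stats::setNames(sprintf("fb_%d", seq_along(vals)),
                         vapply(vals, sbml_num, character(1)))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1"',
                   ' fbc:required="false">'), SBML_CORE_NS, SBML_FBC_NS),
    '  <model id="model" fbc:strict="true">',
    "    <listOfCompartments>",
    sprintf('      <compartment id="%s" constant="true"/>', xml_esc(comps)),
    "    </listOfCompartments>",
    "    <listOfSpecies>")
  for (i in seq_along(net$species_ids))
    lines <- c(lines, sprintf(
      paste0('      <species id="%s" name="%s" compartment="%s"',
             ' hasOnlySubstanceUnits="false" boundaryCondition="false"',
             ' constant="false"/>'),
      xml_esc(net$species_ids[i]), xml_esc(net$species_meta$name[i]),
      xml_esc(net$species_meta$compartment[i])))
  lines <- c(lines, "    </listOfSpecies>", "    <listOfParameters>",
             sprintf('      <parameter id="%s" value="%s" constant="true"/>',
                     pid, names(pid)),
             "    </listOfParameters>", "    <listOfReactions>")
  for (j in seq_along(net$reaction_ids)) {
    col <- net$stoich[, j]
    lo <- pid[[sbml_num(net$lb[j])]]
    hi <- pid[[sbml_num(net$ub[j])]]
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s" reversible="%s" fast="false"',
             ' fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      xml_esc(net$reaction_ids[j]),
      if (net$lb[j] < 0) "true" else "false", lo, hi))
    for (side in c(-1, 1)) {
      idx <- which(sign(col) == side)
      if (length(idx)) {
        tag <- if (side < 0) "listOfReactants" else "listOfProducts"
        lines <- c(lines, sprintf("        <%s>", tag), sprintf(
          paste0('          <speciesReference species="%s"',
                 ' stoichiometry="%s" constant="true"/>'),
          xml_esc(net$species_ids[idx]),
          vapply(abs(col[idx]), sbml_num, character(1))),
          sprintf("        </%s>", tag))
      }
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>")
  obj_idx <- which(net$objective_coeffs != 0)
  lines <- c(lines,
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    "        <fbc:listOfFluxObjectives>",
    if (length(obj_idx)) sprintf(
      paste0('          <fbc:fluxObjective fbc:reaction="%s"',
             ' fbc:coefficient="%s"/>'),
      xml_esc(net$reaction_ids[obj_idx]),
      vapply(net$objective_coeffs[obj_idx], sbml_num, character(1))),
    "        </fbc:listOfFluxObjectives>",
    "      </fbc:objective>",
    "    </fbc:listOfObjectives>",
    "  </model>", "</sbml>")
  writeLines(lines, path)
}

parse_sbml_num <- function(txt) {
  if (is.na(txt)) return(NA_real_)
  if (txt == "INF") return(Inf)
  if (txt == "-INF") return(-Inf)
  as.numeric(txt)
}

## fetch an attribute that may or may not carry the fbc: prefix,
## depending on the writing tool
attr_fbc <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- grep(paste0("(^|:)", name, "$"), names(at))
  if (length(hit)) at[[hit[1]]] else NA_character_
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in ", path,
                                           ": ", conditionMessage(e)))
  sp_nodes <- xml2::xml_find_all(doc, "//*[local-name()='species']")
  if (length(sp_nodes) == 0L) stop("SBML model contains no species")
  species <- xml2::xml_attr(sp_nodes, "id")
  meta <- data.frame(
    id = species,
    name = ifelse(is.na(xml2::xml_attr(sp_nodes, "name")), species,
                  xml2::xml_attr(sp_nodes, "name")),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    stringsAsFactors = FALSE)
  par_nodes <- xml2::xml_find_all(doc, "//*[local-name()='parameter']")
  par_val <- stats::setNames(
    vapply(xml2::xml_attr(par_nodes, "value"), parse_sbml_num, numeric(1)),
    xml2::xml_attr(par_nodes, "id"))
  rx_nodes <- xml2::xml_find_all(
    doc, "//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (length(rx_nodes) == 0L) stop("SBML model contains no reactions")
  rxn_ids <- xml2::xml_attr(rx_nodes, "id")
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  lb <- ub <- numeric(length(rx_nodes))
  for (j in seq_along(rx_nodes)) {
    for (side in c(reactants = -1, products = +1)) {
      tag <- if (side < 0) "listOfReactants" else "listOfProducts"
      refs <- xml2::xml_find_all(rx_nodes[[j]], sprintf(
        "./*[local-name()='%s']/*[local-name()='speciesReference']", tag))
      if (length(refs)) {
        sp <- xml2::xml_attr(refs, "species")
        idx <- match(sp, species)
        if (anyNA(idx))
          stop("reaction '", rxn_ids[j], "' references unknown species ",
               sp[is.na(idx)][1])
        st <- xml2::xml_attr(refs, "stoichiometry")
        st[is.na(st)] <- "1"
        ii <- c(ii, idx); jj <- c(jj, rep(j, length(refs)))
        xx <- c(xx, side * as.numeric(st))
      }
    }
    lo_ref <- attr_fbc(rx_nodes[[j]], "lowerFluxBound")
    hi_ref <- attr_fbc(rx_nodes[[j]], "upperFluxBound")
    lb[j] <- if (!is.na(lo_ref) && lo_ref %in% names(par_val))
      par_val[[lo_ref]] else -Inf
    ub[j] <- if (!is.na(hi_ref) && hi_ref %in% names(par_val))
      par_val[[hi_ref]] else Inf
    ## fall back on the reversible flag when no fbc bounds are present
    if (is.na(lo_ref) &&
        identical(xml2::xml_attr(rx_nodes[[j]], "reversible"), "false"))
      lb[j] <- 0
  }
  obj <- stats::setNames(numeric(length(rxn_ids)), rxn_ids)
  fo <- xml2::xml_find_all(doc, "//*[local-name()='fluxObjective']")
  for (node in fo) {
    rid <- attr_fbc(node, "reaction")
    cf <- parse_sbml_num(attr_fbc(node, "coefficient"))
    if (!is.na(rid) && rid %in% rxn_ids) obj[rid] <- cf
  }
  ## merge repeated species references within a side
  key <- paste(ii, jj)
  if (anyDuplicated(key)) {
    agg <- rowsum(xx, key)
    parts <- do.call(rbind, strsplit(rownames(agg), " "))
    ii <- as.integer(parts[, 1]); jj <- as.integer(parts[, 2])
    xx <- as.numeric(agg)
  }
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(species), length(rxn_ids)),
                            dimnames = list(species, rxn_ids))
  metabolic_network(S, lb = lb, ub = ub, objective = obj,
                    species_meta = meta)
}
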