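#' Construct a diurnal configuration
#'
#' Declares how a base metabolic network is replicated over the diurnal
#' cycle: the ordered phases with their durations and per-phase bound
#' overrides, which species are carried over between phases (storage
#' metabolites and any functional biomass that must survive the night),
#' which carry-over species may additionally be exported out of the cycle
#' for long-term accumulation, and the objective weights of the extended
#' problem.
#'
#' The validated core path supports exactly two phases (light then dark).
#' Durations are in hours; bound overrides are in flux units of the base
#' model and are rescaled to concentration changes when the extended
#' problem is assembled.
#'
#' @param phases list of phases, each a list with \code{name},
#'   \code{duration} (h, > 0) and optional \code{bounds}, a named list
#'   \code{reaction_id -> c(lb, ub)}.
#' @param carryover_species character vector of species transferable
#'   between phases.
#' @param exportable_species subset of \code{carryover_species} given an
#'   export column (lower bound 0: accumulation leaves the system).
#' @param objective named numeric vector; names are either
#'   \code{"<phase>:<reaction_id>"} or \code{"export:<species_id>"}. When
#'   empty, weight 1 is placed on every export column (or, if there are
#'   none, the base model's objective coefficients are used in each phase).
#' @param transfer_bounds optional named list \code{species -> c(lb, ub)}
#'   bounding the transfer amount; default unbounded in both directions
#'   (transfers are reversible).
#' @param component_labels optional named character vector over
#'   \code{carryover_species} with values \code{"functional"} or
#'   \code{"storage"}, used when reporting the transition biomass
#'   composition; default labels exportable species functional and the
#'   rest storage.
#' @return an object of class \code{diurnal_config}.
#' @export
diurnal_config <- function(phases, carryover_species,
                           exportable_species = character(),
                           objective = numeric(0),
                           transfer_bounds = NULL,
                           component_labels = NULL) {
  if (!is.list(phases) || length(phases) < 1L)
    stop("phases must be a non-empty list")
  phases <- lapply(phases, function(ph) {
    if (is.null(ph$name) || is.null(ph$duration))
      stop("each phase needs 'name' and 'duration'")
    ph$duration <- as.numeric(ph$duration)
    if (!is.finite(ph$duration) || ph$duration <= 0)
      stop("phase '", ph$name, "' has nonpositive duration")
    if (is.null(ph$bounds)) ph$bounds <- list()
    ph$bounds <- lapply(ph$bounds, function(b) {
      b <- as.numeric(b)
      if (length(b) != 2L || b[1] > b[2])
        stop("bound override in phase '", ph$name,
             "' must be c(lb, ub) with lb <= ub")
      b
    })
    ph[c("name", "duration", "bounds")]
  })
  nm <- vapply(phases, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate phase name: ", nm[duplicated(nm)][1])
  carryover_species <- as.character(carryover_species)
  exportable_species <- as.character(exportable_species)
  extra <- setdiff(exportable_species, carryover_species)
  if (length(extra))
    stop("exportable species not in carryover list: ",
         paste(extra, collapse = ", "))
  if (!is.null(transfer_bounds)) {
    bad <- setdiff(names(transfer_bounds), carryover_species)
    if (length(bad))
      stop("transfer bound for non-carryover species: ",
           paste(bad, collapse = ", "))
  }
  if (is.null(component_labels)) {
    component_labels <- stats::setNames(
      ifelse(carryover_species %in% exportable_species,
             "functional", "storage"),
      carryover_species)
  } else {
    component_labels <- unlist(component_labels)
    if (!all(names(component_labels) %in% carryover_species) ||
        !all(component_labels %in% c("functional", "storage")))
      stop("component_labels must map carryover species to",
           " 'functional' or 'storage'")
  }
  if (length(objective)) {
    objective <- unlist(objective)
    if (is.null(names(objective)) || any(names(objective) == ""))
      stop("objective entries must be named '<phase>:<reaction>'",
           " or 'export:<species>'")
  }
  structure(list(phases = phases,
                 carryover_species = carryover_species,
                 exportable_species = exportable_species,
                 objective = objective,
                 transfer_bounds = transfer_bounds %||% list(),
                 component_labels = component_labels),
            class = "diurnal_config")
}

#' @export
print.diurnal_config <- function(x, ...) {
  cat("Diurnal configuration:\n")
  for (ph in x$phases)
    cat(sprintf("  phase %-8s %g h, %d bound override(s)\n",
                ph$name, ph$duration, length(ph$bounds)))
  cat("  carry-over:", paste(x$carryover_species, collapse = ", "), "\n")
  cat("  exportable:", paste(x$exportable_species, collapse = ", "), "\n")
  invisible(x)
}

#' Read a diurnal configuration from YAML or JSON
#'
#' Expected keys: \code{phases} (list with \code{name}, \code{duration},
#' optional \code{bounds}), \code{carryover_species},
#' \code{exportable_species}, optional \code{objective},
#' \code{transfer_bounds} and \code{component_labels}. If \code{network}
#' is supplied, species and reaction references are checked against it.
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @param network optional \code{metabolic_network} to validate
#'   identifiers against.
#' @return a \code{diurnal_config}.
#' @export
read_diurnal_config <- function(path, network = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext == "json") jsonlite::read_json(path)
         else yaml::read_yaml(path)
  if (is.null(doc$phases) || is.null(doc$carryover_species))
    stop("config lacks required keys 'phases' and 'carryover_species'")
  cfg <- diurnal_config(
    phases = doc$phases,
    carryover_species = unlist(doc$carryover_species),
    exportable_species = unlist(doc$exportable_species) %||% character(),
    objective = doc$objective %||% numeric(0),
    transfer_bounds = doc$transfer_bounds,
    component_labels = doc$component_labels)
  if (!is.null(network)) validate_config(cfg, network)
  cfg
}

#' Validate a configuration against a network
#'
#' Checks that every species and reaction the configuration refers to
#' exists in the model.
#'
#' @param config a \code{diurnal_config}.
#' @param network a \code{metabolic_network}.
#' @return the config, invisibly.
#' @export
validate_config <- function(config, network) {
  bad <- setdiff(config$carryover_species, network$species_ids)
  if (length(bad))
    stop("carryover species not in model: ", paste(bad, collapse = ", "))
  for (ph in config$phases) {
    badr <- setdiff(names(ph$bounds), network$reaction_ids)
    if (length(badr))
      stop("bound override in phase '", ph$name,
           "' for unknown reaction: ", paste(badr, collapse = ", "))
  }
  invisible(config)
}

#' Write a diurnal configuration to YAML
#'
#' @param config a \code{diurnal_config}.
#' @param path output file (.yml/.yaml).
#' @return \code{path}, invisibly.
#' @export
write_diurnal_config <- function(config, path) {
  doc <- list(
    phases = lapply(config$phases, function(ph)
      list(name = ph$name, duration = ph$duration,
           bounds = ph$bounds)),
    carryover_species = config$carryover_species,
    exportable_species = config$exportable_species,
    objective = as.list(config$objective),
    transfer_bounds = config$transfer_bounds,
    component_labels = as.list(config$component_labels))
  yaml::write_yaml(doc, path)
  invisible(path)
}
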