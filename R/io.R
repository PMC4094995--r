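# Native JSON model dialect.
#
# Model file:    {metabolites: [{id, name, compartment}],
#                 reactions: [{id, stoichiometry: {met: coeff}, reversible,
#                              lower_bound, upper_bound, kind,
#                              taxonomic_status}],
#                 biomass: "reaction-id",
#                 nutrients: [{id, max_uptake}], secretions: ["id", ...]}
# Pool file:     {reactions: [{...reaction fields..., cost: number|null}]}
# Class map:     {"class-id": ["member", ...]
#                 or {"members": [...], "paired_with": "other-class-id"}}
#
# Unbounded fluxes are serialized as JSON null and read back as Inf.

json_num <- function(x) if (is.null(x) || is.na(x)) Inf else as.numeric(x)

rxn_from_json <- function(j) {
  st <- unlist(j$stoichiometry)
  if (is.null(st)) st <- numeric(0)
  reaction(id = j$id, stoichiometry = st,
           reversible = isTRUE(j$reversible),
           lower_bound = if (is.null(j$lower_bound)) {
             if (isTRUE(j$reversible)) -Inf else 0
           } else if (is.na(j$lower_bound)) -Inf else as.numeric(j$lower_bound),
           upper_bound = json_num(j$upper_bound),
           kind = if (is.null(j$kind)) "enzymatic" else j$kind,
           taxonomic_status = if (is.null(j$taxonomic_status))
             "not_applicable" else j$taxonomic_status)
}

rxn_to_json <- function(r) {
  list(id = r$id,
       stoichiometry = as.list(r$stoichiometry),
       reversible = r$reversible,
       lower_bound = if (is.infinite(r$lower_bound)) NULL else r$lower_bound,
       upper_bound = if (is.infinite(r$upper_bound)) NULL else r$upper_bound,
       kind = r$kind, taxonomic_status = r$taxonomic_status)
}

#' Read a metabolic model from a JSON file
#'
#' Reads the native JSON model dialect (see the package vignette for the
#' schema). Unknown nutrient/secretion ids and structural violations are an
#' error at load time.
#'
#' @param path Path to a JSON model file.
#' @return An `fgf_model`.
#' @seealso [write_model()], [validate_model()]
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path)
  mets <- lapply(j$metabolites, function(m)
    metabolite(m$id, if (is.null(m$name)) m$id else m$name,
               if (is.null(m$compartment)) "c" else m$compartment))
  rxns <- lapply(j$reactions, rxn_from_json)
  nut <- numeric(0)
  if (length(j$nutrients))
    nut <- setNames(vapply(j$nutrients, function(n) json_num(n$max_uptake), 0),
                    vapply(j$nutrients, `[[`, "", "id"))
  model <- metabolic_model(mets, rxns, biomass = j$biomass, nutrients = nut,
                           secretions = unlist(j$secretions) %||% character(0))
  diags <- validate_model(model)
  if (length(diags))
    stop("invalid model '", path, "':\n  ", paste(diags, collapse = "\n  "))
  model
}

#' Write a metabolic model to a JSON file
#' @param model An `fgf_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  j <- list(
    metabolites = lapply(model$metabolites, function(m)
      list(id = m$id, name = m$name, compartment = m$compartment)),
    reactions = lapply(model$reactions, rxn_to_json),
    biomass = model$biomass,
    nutrients = lapply(names(model$nutrients), function(n)
      list(id = n, max_uptake = if (is.infinite(model$nutrients[[n]])) NULL
           else model$nutrients[[n]])),
    secretions = as.list(model$secretions))
  names(j$metabolites) <- NULL; names(j$reactions) <- NULL
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a candidate pool from a JSON file
#'
#' Entries use the same reaction schema as models plus a `cost` field;
#' `cost: null` marks the cost as unassigned (to be filled by
#' [assign_costs()]).
#'
#' @param path Path to a JSON pool file.
#' @param model Optional `fgf_model`; if given, candidate ids colliding with
#'   model reaction ids are an error at load time.
#' @return An `fgf_pool`.
#' @export
read_pool <- function(path, model = NULL) {
  j <- jsonlite::read_json(path)
  entries <- if (!is.null(j$reactions)) j$reactions else j
  cands <- lapply(entries, rxn_from_json)
  costs <- vapply(entries, function(e)
    if (is.null(e$cost)) NA_real_ else as.numeric(e$cost), 0)
  pool <- candidate_pool(cands, costs)
  if (!is.null(model)) {
    clash <- intersect(names(pool$candidates), names(model$reactions))
    if (length(clash))
      stop("candidate ids collide with model reaction ids: ",
           paste(clash, collapse = ", "))
  }
  pool
}

#' Write a candidate pool to a JSON file
#' @param pool An `fgf_pool`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pool <- function(pool, path) {
  j <- list(reactions = lapply(names(pool$candidates), function(id) {
    e <- rxn_to_json(pool$candidates[[id]])
    e$cost <- if (is.na(pool$costs[[id]])) NULL else pool$costs[[id]]
    e
  }))
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a compound class map from a JSON file
#'
#' A class map drives [instantiate_generic()]: each compound-class id maps to
#' the concrete metabolite ids standing in for it. An entry may be a plain
#' member array, or an object `{"members": [...], "paired_with": "class"}`
#' declaring that its members correspond positionally to another class's
#' members (e.g. an alcohol class and its phosphorylated counterparts), in
#' which case both classes are substituted in lockstep.
#'
#' @param path Path to a JSON class-map file.
#' @return An object of class `fgf_class_map`.
#' @export
read_class_map <- function(path) {
  j <- jsonlite::read_json(path)
  members <- list(); paired <- character(0)
  for (cl in names(j)) {
    e <- j[[cl]]
    if (is.list(e) && !is.null(e$members)) {
      members[[cl]] <- unlist(e$members)
      if (!is.null(e$paired_with)) paired[[cl]] <- e$paired_with
    } else {
      members[[cl]] <- unlist(e)
    }
  }
  class_map(members, paired)
}

#' Construct a compound class map
#'
#' @param members Named list: class id -> character vector of concrete
#'   metabolite ids.
#' @param paired_with Named character vector: class id -> id of the class it
#'   is positionally paired with (substituted in lockstep).
#' @return An object of class `fgf_class_map`.
#' @seealso [instantiate_generic()], [read_class_map()]
#' @export
class_map <- function(members, paired_with = character(0)) {
  stopifnot(is.list(members), !is.null(names(members)))
  for (cl in names(paired_with)) {
    other <- paired_with[[cl]]
    if (!other %in% names(members))
      stop("class '", cl, "' paired with unknown class '", other, "'")
    if (length(members[[cl]]) != length(members[[other]]))
      stop("paired classes '", cl, "' and '", other,
           "' have different member counts")
  }
  structure(list(members = members, paired_with = paired_with),
            class = "fgf_class_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
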