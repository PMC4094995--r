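#' Reaction kinds and taxonomic statuses
#'
#' Controlled vocabularies used throughout the package. `kind` distinguishes
#' ordinary enzymatic reactions from spontaneous (non-enzymatic) reactions,
#' boundary exchange pseudo-reactions and the biomass pseudo-reaction.
#' `taxonomic_status` records whether an enzymatic reaction is known inside
#' the taxonomic range of the organism being modelled; it drives default
#' candidate costs (see [cost_scheme()]).
#'
#' @name vocabularies
#' @keywords internal
NULL

REACTION_KINDS <- c("spontaneous", "enzymatic", "exchange", "biomass")
TAXONOMIC_STATUSES <- c("in_range", "unknown", "out_of_range", "not_applicable")

#' Create a metabolite
#'
#' @param id Unique non-empty string identifier.
#' @param name Free-text name (defaults to `id`).
#' @param compartment Compartment tag; single-compartment models use the
#'   default `"c"`. Tags are carried through but not interpreted.
#' @return An object of class `fgf_metabolite`.
#' @export
metabolite <- function(id, name = id, compartment = "c") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(id = id, name = name, compartment = compartment),
            class = "fgf_metabolite")
}

#' Create a reaction
#'
#' Stoichiometric coefficients are signed doubles: negative for consumed
#' metabolites, positive for produced ones. Flux bounds are in mmol/g/h;
#' `upper_bound = Inf` is accepted and capped internally when LPs are built.
#'
#' @param id Unique non-empty string identifier (case-sensitive, opaque).
#' @param stoichiometry Named numeric vector, metabolite id -> coefficient.
#'   Must be non-empty except for exchange reactions.
#' @param reversible Logical; reversible reactions are split before any LP
#'   is built (see [split_reversible()]).
#' @param lower_bound,upper_bound Flux bounds. Irreversible reactions must
#'   have `lower_bound >= 0`.
#' @param kind One of `"spontaneous"`, `"enzymatic"`, `"exchange"`,
#'   `"biomass"`.
#' @param taxonomic_status One of `"in_range"`, `"unknown"`,
#'   `"out_of_range"`, `"not_applicable"`.
#' @return An object of class `fgf_reaction`.
#' @export
reaction <- function(id, stoichiometry, reversible = FALSE,
                     lower_bound = if (reversible) -Inf else 0,
                     upper_bound = Inf,
                     kind = "enzymatic", taxonomic_status = "not_applicable") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  kind <- match.arg(kind, REACTION_KINDS)
  taxonomic_status <- match.arg(taxonomic_status, TAXONOMIC_STATUSES)
  if (length(stoichiometry)) {
    stopifnot(is.numeric(stoichiometry), !is.null(names(stoichiometry)),
              all(nzchar(names(stoichiometry))))
    stoichiometry <- stoichiometry[stoichiometry != 0]
  }
  if (!length(stoichiometry) && kind != "exchange")
    stop("reaction '", id, "': empty stoichiometry (only exchange reactions may touch a single metabolite or none)")
  if (anyDuplicated(names(stoichiometry)))
    stop("reaction '", id, "': duplicated metabolite in stoichiometry")
  stopifnot(length(lower_bound) == 1L, length(upper_bound) == 1L,
            lower_bound <= upper_bound)
  structure(list(id = id, stoichiometry = stoichiometry,
                 reversible = isTRUE(reversible),
                 lower_bound = as.numeric(lower_bound),
                 upper_bound = as.numeric(upper_bound),
                 kind = kind, taxonomic_status = taxonomic_status),
            class = "fgf_reaction")
}

#' Create a metabolic model
#'
#' A model bundles the reaction network `N`, the biomass pseudo-reaction and
#' the growth environment (importable nutrients with uptake caps, exportable
#' secretions). Exchange pseudo-reactions for the environment are added later
#' by [attach_environment()].
#'
#' @param metabolites List of [metabolite()] objects (or a data.frame with
#'   columns `id`, `name`, `compartment`).
#' @param reactions List of [reaction()] objects; exactly one must have kind
#'   `"biomass"` unless `biomass` names it explicitly.
#' @param biomass Id of the biomass reaction.
#' @param nutrients Named numeric vector: metabolite id -> maximum uptake
#'   flux (mmol/g/h; `Inf` for uncapped).
#' @param secretions Character vector of exportable metabolite ids.
#' @return An object of class `fgf_model`.
#' @seealso [validate_model()], [read_model()]
#' @export
metabolic_model <- function(metabolites, reactions, biomass,
                            nutrients = numeric(0),
                            secretions = character(0)) {
  if (is.data.frame(metabolites)) {
    metabolites <- lapply(seq_len(nrow(metabolites)), function(i)
      metabolite(metabolites$id[i],
                 if ("name" %in% names(metabolites)) metabolites$name[i] else metabolites$id[i],
                 if ("compartment" %in% names(metabolites)) metabolites$compartment[i] else "c"))
  }
  stopifnot(all(vapply(metabolites, inherits, TRUE, "fgf_metabolite")),
            all(vapply(reactions, inherits, TRUE, "fgf_reaction")))
  names(metabolites) <- vapply(metabolites, `[[`, "", "id")
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  if (length(nutrients) && is.null(names(nutrients)))
    stop("nutrients must be a named numeric vector of uptake caps")
  structure(list(metabolites = metabolites, reactions = reactions,
                 biomass = biomass,
                 nutrients = nutrients,
                 secretions = as.character(secretions)),
            class = "fgf_model")
}

#' Create a candidate reaction pool
#'
#' The pool `M` of reactions considered for addition during gap-filling.
#' Each candidate carries a non-negative cost `c_r`; `NA` marks a cost left
#' for [assign_costs()] to fill from a [cost_scheme()].
#'
#' @param candidates List of [reaction()] objects.
#' @param costs Numeric vector of per-candidate costs (recycled names from
#'   `candidates`; `NA` = unassigned). Default all `NA`.
#' @return An object of class `fgf_pool`.
#' @export
candidate_pool <- function(candidates, costs = rep(NA_real_, length(candidates))) {
  stopifnot(all(vapply(candidates, inherits, TRUE, "fgf_reaction")),
            length(costs) == length(candidates))
  ids <- vapply(candidates, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate candidate reaction ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!is.na(costs) & costs < 0))
    stop("candidate costs must be non-negative")
  names(candidates) <- ids
  structure(list(candidates = candidates,
                 costs = setNames(as.numeric(costs), ids)),
            class = "fgf_pool")
}

#' Number of candidates in a pool
#' @param pool An `fgf_pool`.
#' @return Integer |M|.
#' @export
pool_size <- function(pool) length(pool$candidates)

#' Validate a metabolic model
#'
#' Checks the structural invariants of a model and returns one diagnostic
#' string per violation (an empty character vector for a well-formed model).
#' Diagnostics, not exceptions: callers decide how strict to be.
#'
#' Checked: duplicate metabolite/reaction ids; reactions referencing unknown
#' metabolite ids; missing or empty biomass reaction; negative lower bound on
#' an irreversible reaction; nutrient/secretion ids absent from the model.
#'
#' @param model An `fgf_model`.
#' @return Character vector of diagnostics (empty if valid).
#' @export
validate_model <- function(model) {
  diags <- character(0)
  mids <- vapply(model$metabolites, `[[`, "", "id")
  rids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(mids))
    diags <- c(diags, paste0("duplicate metabolite id: ",
                             paste(unique(mids[duplicated(mids)]), collapse = ", ")))
  if (anyDuplicated(rids))
    diags <- c(diags, paste0("duplicate reaction id: ",
                             paste(unique(rids[duplicated(rids)]), collapse = ", ")))
  for (r in model$reactions) {
    unknown <- setdiff(names(r$stoichiometry), mids)
    if (length(unknown))
      diags <- c(diags, paste0("reaction '", r$id,
                               "' references unknown metabolite id: ",
                               paste(unknown, collapse = ", ")))
    if (!r$reversible && r$lower_bound < 0)
      diags <- c(diags, paste0("irreversible reaction '", r$id,
                               "' has negative lower bound ", r$lower_bound))
  }
  bm <- model$reactions[[model$biomass]]
  if (is.null(bm)) {
    diags <- c(diags, paste0("biomass reaction '", model$biomass, "' not found"))
  } else {
    if (!any(bm$stoichiometry < 0))
      diags <- c(diags, "empty biomass: biomass reaction consumes no metabolite")
    if (bm$kind != "biomass")
      diags <- c(diags, paste0("biomass reaction '", model$biomass,
                               "' has kind '", bm$kind, "', expected 'biomass'"))
  }
  badnut <- setdiff(names(model$nutrients), mids)
  if (length(badnut))
    diags <- c(diags, paste0("nutrient id not in model metabolites: ",
                             paste(badnut, collapse = ", ")))
  badsec <- setdiff(model$secretions, mids)
  if (length(badsec))
    diags <- c(diags, paste0("secretion id not in model metabolites: ",
                             paste(badsec, collapse = ", ")))
  diags
}

#' Validate a candidate pool against a model
#'
#' Candidate ids must be disjoint from model reaction ids (a collision is an
#' error at load time elsewhere; here it is reported as a diagnostic).
#' Candidates duplicating the stoichiometry of an existing model reaction
#' under a different id are allowed but noted.
#'
#' @param pool An `fgf_pool`.
#' @param model An `fgf_model`, or `NULL` to check the pool alone.
#' @return Character vector of diagnostics (empty if valid).
#' @export
validate_pool <- function(pool, model = NULL) {
  diags <- character(0)
  if (any(!is.na(pool$costs) & pool$costs < 0))
    diags <- c(diags, "negative candidate cost")
  if (!is.null(model)) {
    clash <- intersect(names(pool$candidates), names(model$reactions))
    if (length(clash))
      diags <- c(diags, paste0("candidate id collides with model reaction id: ",
                               paste(clash, collapse = ", ")))
    sig <- function(r) paste(names(r$stoichiometry)[order(names(r$stoichiometry))],
                             r$stoichiometry[order(names(r$stoichiometry))],
                             collapse = ";")
    msigs <- vapply(model$reactions, sig, "")
    for (cand in pool$candidates) {
      hit <- names(model$reactions)[msigs == sig(cand)]
      if (length(hit))
        diags <- c(diags, paste0("note: candidate '", cand$id,
                                 "' duplicates stoichiometry of model reaction '",
                                 hit[1L], "'"))
    }
  }
  diags
}

#' @exportS3Method base::print
print.fgf_model <- function(x, ...) {
  cat("Metabolic model:", length(x$metabolites), "metabolites,",
      length(x$reactions), "reactions\n")
  cat("  biomass:", x$biomass, "\n")
  cat("  nutrients:", if (length(x$nutrients))
    paste0(names(x$nutrients), " (cap ", x$nutrients, ")", collapse = ", ")
    else "none", "\n")
  cat("  secretions:", if (length(x$secretions))
    paste(x$secretions, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' @exportS3Method base::print
print.fgf_pool <- function(x, ...) {
  n <- pool_size(x)
  cat("Candidate pool: ", n, " reactions (",
      sum(is.na(x$costs)), " without assigned cost)\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::print
print.fgf_reaction <- function(x, ...) {
  s <- x$stoichiometry
  lhs <- s[s < 0]; rhs <- s[s > 0]
  fmt <- function(v) if (!length(v)) "" else
    paste(ifelse(abs(v) == 1, names(v), paste(abs(v), names(v))), collapse = " + ")
  cat(x$id, ": ", fmt(lhs), if (x$reversible) " <=> " else " --> ", fmt(rhs),
      "  [", x$lower_bound, ", ", x$upper_bound, "] ", x$kind, "\n", sep = "")
  invisible(x)
}
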