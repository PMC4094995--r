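#' Split reversible reactions into irreversible pairs
#'
#' Standard FBA preprocessing: every reversible reaction `r` is replaced by
#' `r_fwd` (same stoichiometry, bounds `[0, ub]`) and `r_rev` (negated
#' stoichiometry, bounds `[0, -lb]` when `lb < 0`, else `[0, ub]`), so that
#' all flux variables become non-negative. Irreversible reactions pass
#' through unchanged. Derived ids are deterministic (`_fwd`/`_rev` suffixes).
#'
#' @param reactions A list of [reaction()] objects (or an `fgf_pool`, in
#'   which case each direction inherits the full parent cost).
#' @return A list of irreversible reactions (or an `fgf_pool`).
#' @export
split_reversible <- function(reactions) {
  if (inherits(reactions, "fgf_pool")) {
    split <- split_reversible(reactions$candidates)
    parent <- vapply(split, function(r) attr(r, "parent") %||% r$id, "")
    return(candidate_pool(split, unname(reactions$costs[parent])))
  }
  ids <- vapply(reactions, `[[`, "", "id")
  out <- list()
  for (r in reactions) {
    if (!r$reversible) {
      out[[length(out) + 1L]] <- r
      next
    }
    for (suffix in c("_fwd", "_rev")) {
      did <- paste0(r$id, suffix)
      if (did %in% ids)
        stop("derived id '", did, "' from splitting '", r$id,
             "' collides with existing reaction id '", did, "'")
    }
    fwd <- reaction(paste0(r$id, "_fwd"), r$stoichiometry, reversible = FALSE,
                    lower_bound = 0, upper_bound = r$upper_bound,
                    kind = r$kind, taxonomic_status = r$taxonomic_status)
    rev_ub <- if (r$lower_bound < 0) -r$lower_bound else r$upper_bound
    rev <- reaction(paste0(r$id, "_rev"), -r$stoichiometry, reversible = FALSE,
                    lower_bound = 0, upper_bound = rev_ub,
                    kind = r$kind, taxonomic_status = r$taxonomic_status)
    attr(fwd, "parent") <- r$id
    attr(rev, "parent") <- r$id
    out[[length(out) + 1L]] <- fwd
    out[[length(out) + 1L]] <- rev
  }
  names(out) <- vapply(out, `[[`, "", "id")
  out
}

#' Instantiate a generic reaction against a class map
#'
#' Reactions written over compound classes (e.g. "an alcohol") are expanded
#' into concrete reactions by substituting each class with its member
#' metabolites. Distinct classes expand by Cartesian product; classes
#' declared `paired_with` each other in the [class_map()] are substituted in
#' lockstep (member i with member i), which keeps chemically coupled pairs
#' such as a compound family and its phosphorylated counterparts coherent.
#' Because stoichiometry is a net coefficient map, a class id occurring on
#' both sides of a reaction is a single entry and is substituted once,
#' i.e. with the same member on both sides.
#'
#' Derived ids are deterministic: parent id plus the chosen member ids.
#'
#' @param rxn A [reaction()] whose stoichiometry may reference class ids.
#' @param classes An `fgf_class_map`.
#' @return A named list of reactions; `list(rxn)` when no class id occurs.
#'   A referenced class with an empty member set drops the reaction and
#'   returns an empty list with a `"warning"` attribute.
#' @export
instantiate_generic <- function(rxn, classes) {
  cls_here <- intersect(names(rxn$stoichiometry), names(classes$members))
  if (!length(cls_here)) return(setNames(list(rxn), rxn$id))
  empty <- cls_here[vapply(classes$members[cls_here], length, 0L) == 0L]
  if (length(empty)) {
    out <- list()
    attr(out, "warning") <- paste0("reaction '", rxn$id,
                                   "' dropped: class '", empty[1L],
                                   "' has no members in the model")
    return(out)
  }
  # group pairing-linked classes present in this reaction
  group_of <- setNames(seq_along(cls_here), cls_here)
  repeat {
    changed <- FALSE
    for (cl in cls_here) {
      other <- classes$paired_with[cl]
      if (!is.na(other) && other %in% cls_here &&
          group_of[[cl]] != group_of[[other]]) {
        group_of[group_of == group_of[[cl]]] <- group_of[[other]]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  groups <- split(cls_here, group_of[cls_here])
  # one index per group, ranging over that group's (common) member count
  sizes <- vapply(groups, function(g) length(classes$members[[g[1L]]]), 0L)
  for (g in groups)
    if (length(unique(vapply(classes$members[g], length, 0L))) != 1L)
      stop("paired classes with different member counts in reaction '",
           rxn$id, "'")
  idx <- do.call(expand.grid, lapply(sizes, seq_len))
  out <- list()
  for (k in seq_len(nrow(idx))) {
    st <- rxn$stoichiometry
    chosen <- character(0)
    for (gi in seq_along(groups)) {
      i <- idx[k, gi]
      for (cl in groups[[gi]]) {
        member <- classes$members[[cl]][i]
        chosen <- c(chosen, member)
        pos <- match(cl, names(st))
        coef <- st[[pos]]
        st <- st[-pos]
        st[member] <- (if (member %in% names(st)) st[[member]] else 0) + coef
      }
    }
    did <- paste(c(rxn$id, chosen), collapse = "__")
    out[[did]] <- reaction(did, st, reversible = rxn$reversible,
                           lower_bound = rxn$lower_bound,
                           upper_bound = rxn$upper_bound,
                           kind = rxn$kind,
                           taxonomic_status = rxn$taxonomic_status)
  }
  out
}

#' Attach growth-environment exchange reactions
#'
#' Adds one uptake exchange per nutrient (`EX_<id>_in`: nothing -> metabolite,
#' upper bound = the nutrient's uptake cap, or the package flux cap when
#' uncapped) and one export exchange per secretion (`EX_<id>_out`:
#' metabolite -> nothing, upper bound = flux cap). Idempotent: exchanges that
#' already exist are left untouched.
#'
#' @param model A validated `fgf_model`.
#' @return The model with exchange reactions attached.
#' @export
attach_environment <- function(model) {
  mids <- names(model$metabolites)
  for (n in names(model$nutrients)) {
    if (!n %in% mids)
      stop("nutrient '", n, "' is not a metabolite of the model")
    ex <- paste0("EX_", n, "_in")
    if (ex %in% names(model$reactions)) next
    cap <- model$nutrients[[n]]
    if (is.infinite(cap)) cap <- fgf_tol$flux_cap
    model$reactions[[ex]] <- reaction(ex, setNames(1, n), reversible = FALSE,
                                      lower_bound = 0, upper_bound = cap,
                                      kind = "exchange")
  }
  for (s in model$secretions) {
    if (!s %in% mids)
      stop("secretion '", s, "' is not a metabolite of the model")
    ex <- paste0("EX_", s, "_out")
    if (ex %in% names(model$reactions)) next
    model$reactions[[ex]] <- reaction(ex, setNames(-1, s), reversible = FALSE,
                                      lower_bound = 0,
                                      upper_bound = fgf_tol$flux_cap,
                                      kind = "exchange")
  }
  model
}

#' Preprocess a model into LP-ready form
#'
#' Pipeline: instantiate generic reactions (if a class map is given), split
#' reversible reactions, attach the growth-environment exchanges. After this
#' every reaction is irreversible with a non-negative lower bound, so all
#' flux variables in subsequent LPs are non-negative.
#'
#' @param model An `fgf_model`.
#' @param classes Optional `fgf_class_map` for generic-reaction expansion.
#' @return The preprocessed model.
#' @seealso [preprocess_pool()]
#' @export
preprocess_model <- function(model, classes = NULL) {
  diags <- validate_model(model)
  if (length(diags))
    stop("invalid model:\n  ", paste(diags, collapse = "\n  "))
  rxns <- model$reactions
  if (!is.null(classes)) {
    rxns <- do.call(c, unname(lapply(rxns, function(r)
      if (r$kind %in% c("biomass", "exchange")) setNames(list(r), r$id)
      else instantiate_generic(r, classes))))
  }
  bm <- rxns[[model$biomass]]
  if (isTRUE(bm$reversible))
    stop("biomass reaction must be irreversible")
  rxns <- split_reversible(rxns)
  model$reactions <- rxns
  attach_environment(model)
}

#' Preprocess a candidate pool into LP-ready form
#'
#' Instantiates generic candidates (if a class map is given) and splits
#' reversible candidates; each direction of a split candidate inherits the
#' full parent cost, so either direction can be selected independently.
#'
#' @param pool An `fgf_pool`.
#' @param classes Optional `fgf_class_map`.
#' @return The preprocessed pool.
#' @export
preprocess_pool <- function(pool, classes = NULL) {
  if (!is.null(classes)) {
    cands <- list(); costs <- numeric(0)
    for (id in names(pool$candidates)) {
      inst <- instantiate_generic(pool$candidates[[id]], classes)
      if (!length(inst) && !is.null(attr(inst, "warning")))
        warning(attr(inst, "warning"), call. = FALSE)
      for (r in inst) {
        cands[[r$id]] <- r
        costs[[r$id]] <- pool$costs[[id]]
      }
    }
    pool <- candidate_pool(cands, unname(costs))
  }
  split_reversible(pool)
}
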