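# Deterministic synthetic benchmark instances: working toy pathway models,
# knockout procedures that provably prohibit growth, and candidate pools
# padded with mass-disconnected decoy reactions. Together these emulate the
# benchmark protocol of starting from a working genome-scale model, removing
# essential reactions until growth is lost, and gap-filling against a large
# reaction-database pool.

#' Generate a working toy pathway model
#'
#' Builds a linear/branched biosynthesis network: one nutrient feeds a chain
#' of `n_metabolites - biomass_size` enzymatic steps whose end branches into
#' `biomass_size` precursor-producing reactions; the biomass reaction
#' consumes one unit of each precursor. Stoichiometric coefficients are
#' drawn from {1, 2} (seeded), keeping LPs well conditioned while exercising
#' non-unit stoichiometry. Every chain and branch reaction is essential, so
#' knockouts of any subset prohibit growth. The model is asserted
#' growth-positive at construction and is identical for identical seeds.
#'
#' @param n_metabolites Total number of metabolites (`>= biomass_size >= 1`).
#' @param biomass_size Number of biomass precursor metabolites.
#' @param seed Integer seed controlling the stoichiometric coefficients.
#' @param nutrient_cap Uptake cap on the nutrient (default 10 mmol/g/h).
#' @return A preprocessed, growth-positive `fgf_model`.
#' @export
make_chain_model <- function(n_metabolites, biomass_size = 1L, seed = 0L,
                             nutrient_cap = 10) {
  if (biomass_size < 1L || n_metabolites < biomass_size + 1L)
    stop("need n_metabolites >= biomass_size + 1 and biomass_size >= 1")
  rng <- local_rng(seed)
  mets <- paste0("C", seq_len(n_metabolites))
  k <- n_metabolites - biomass_size # chain part: C1 .. Ck
  rxns <- list()
  coef <- function() rng(2L) # 1 or 2
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      id <- paste0("R", i)
      rxns[[id]] <- reaction(id,
        setNames(c(-1, coef()), mets[c(i, i + 1L)]),
        kind = "enzymatic", taxonomic_status = "in_range")
    }
  }
  precursors <- mets[(k + 1L):n_metabolites]
  for (j in seq_len(biomass_size)) {
    id <- paste0("B", j)
    rxns[[id]] <- reaction(id,
      setNames(c(-1, coef()), c(mets[k], precursors[j])),
      kind = "enzymatic", taxonomic_status = "in_range")
  }
  rxns[["BIOMASS"]] <- reaction("BIOMASS",
    setNames(rep(-1, biomass_size), precursors), kind = "biomass")
  model <- metabolic_model(
    lapply(mets, metabolite),
    rxns, biomass = "BIOMASS",
    nutrients = setNames(nutrient_cap, mets[1L]))
  model <- preprocess_model(model)
  growth <- fba(model)$biomass_flux
  stopifnot(growth > fgf_tol$eps_growth) # by construction
  attr(model, "seed") <- seed
  model
}

#' Knock reactions out of a working model
#'
#' Removes the given reactions and asserts that the removal prohibits
#' growth (maximum biomass at or below `eps_growth`); a knockout that
#' leaves the model growing (e.g. a redundant reaction with a parallel
#' path) is an error reporting the achieved biomass. The removed reactions
#' become the initial candidate pool, with costs left unassigned.
#'
#' @param model A preprocessed, growth-positive `fgf_model`.
#' @param reaction_ids Ids of model reactions to remove (not the biomass or
#'   an exchange reaction).
#' @param eps_growth Growth threshold for the prohibition assertion.
#' @return `list(model = incomplete model, pool = fgf_pool of the removed
#'   reactions)`.
#' @export
knockout <- function(model, reaction_ids, eps_growth = fgf_tol$eps_growth) {
  reaction_ids <- as.character(reaction_ids)
  missing_ <- setdiff(reaction_ids, names(model$reactions))
  if (length(missing_))
    stop("unknown reaction ids: ", paste(missing_, collapse = ", "))
  kinds <- vapply(model$reactions[reaction_ids], `[[`, "", "kind")
  if (any(kinds %in% c("biomass", "exchange")))
    stop("cannot knock out biomass or exchange reactions")
  removed <- model$reactions[reaction_ids]
  model$reactions <- model$reactions[setdiff(names(model$reactions),
                                             reaction_ids)]
  growth <- fba(model)$biomass_flux
  if (is.na(growth) || growth > eps_growth)
    stop("knockout did not prohibit growth (achieved biomass ",
         signif(growth, 6), ")")
  list(model = model, pool = candidate_pool(unname(removed)))
}

#' Pad a candidate pool with decoy reactions
#'
#' Adds `n_decoys` deterministic pseudo-random reactions standing in for the
#' bulk of a reaction database. Decoys touch either a model metabolite and a
#' fresh dead-end metabolite, or two fresh dead-end metabolites, with
#' coefficients in {1, 2}; being mass-disconnected from any balanced route,
#' they can never carry steady-state flux, so the knocked-out reaction set
#' always remains a completion of the instance. Kinds and taxonomic
#' statuses are randomized so decoys exercise the whole cost scheme.
#'
#' @param pool An `fgf_pool` (e.g. from [knockout()]).
#' @param model The incomplete `fgf_model` the pool targets.
#' @param n_decoys Number of decoys to add (`>= 0`).
#' @param seed Integer seed; identical seeds give identical pools.
#' @return The enlarged `fgf_pool`.
#' @export
add_decoys <- function(pool, model, n_decoys, seed = 0L) {
  stopifnot(n_decoys >= 0)
  if (n_decoys == 0L) return(pool)
  rng <- local_rng(seed)
  mets <- names(model$metabolites)
  cands <- pool$candidates
  costs <- pool$costs
  statuses <- c("in_range", "unknown", "out_of_range")
  for (i in seq_len(n_decoys)) {
    id <- paste0("DCY", i)
    dead <- paste0("X", i) # fresh metabolite, unknown to the model
    st <- if (rng(2L) == 1L) {
      setNames(c(-1, rng(2L)), c(mets[rng(length(mets))], dead))
    } else if (rng(2L) == 1L) {
      setNames(c(-rng(2L), 1), c(dead, mets[rng(length(mets))]))
    } else {
      setNames(c(-1, rng(2L)), c(dead, paste0("X", i, "b")))
    }
    spont <- rng(6L) == 1L
    cands[[id]] <- reaction(
      id, st, kind = if (spont) "spontaneous" else "enzymatic",
      taxonomic_status = if (spont) "not_applicable"
                         else statuses[rng(3L)])
    costs[[id]] <- NA_real_
  }
  candidate_pool(cands, unname(costs))
}

# Small deterministic PRNG (linear congruential, Numerical Recipes
# constants) so fixture generation never touches R's global RNG stream.
local_rng <- function(seed) {
  state <- as.double(seed %% 2^31)
  function(n) {
    state <<- (1664525 * state + 1013904223) %% 2^32
    as.integer(state %% n) + 1L
  }
}

#' Generate a complete gap-filling benchmark instance
#'
#' Convenience wrapper chaining [make_chain_model()], [knockout()] of a
#' seeded choice of essential reactions, [add_decoys()] and
#' [assign_costs()]. Every instance satisfies the three benchmark
#' guarantees: the complete model grows, the incomplete model does not, and
#' the knocked-out set restores growth.
#'
#' @param n_metabolites,biomass_size Passed to [make_chain_model()].
#' @param n_knockouts Number of essential reactions to remove.
#' @param n_decoys Number of decoy candidates to add.
#' @param seed Integer seed for the whole instance.
#' @param scheme [cost_scheme()] for candidate costs.
#' @return `list(complete, model, pool, knocked_out)` where `model` is the
#'   incomplete model and `knocked_out` the removed reaction ids.
#' @export
make_instance <- function(n_metabolites = 8L, biomass_size = 1L,
                          n_knockouts = 1L, n_decoys = 0L, seed = 0L,
                          scheme = default_cost_scheme()) {
  complete <- make_chain_model(n_metabolites, biomass_size, seed)
  essential <- setdiff(names(complete$reactions),
                       c("BIOMASS", grep("^EX_", names(complete$reactions),
                                         value = TRUE)))
  if (n_knockouts > length(essential))
    stop("model has only ", length(essential), " knockable reactions")
  rng <- local_rng(seed + 1)
  ko <- essential[sort(sample_without_replacement(rng, length(essential),
                                                  n_knockouts))]
  inst <- knockout(complete, ko)
  pool <- add_decoys(inst$pool, inst$model, n_decoys, seed + 2)
  pool <- assign_costs(pool, scheme)
  list(complete = complete, model = inst$model, pool = pool,
       knocked_out = ko)
}

sample_without_replacement <- function(rng, n, k) {
  pool <- seq_len(n)
  out <- integer(k)
  for (i in seq_len(k)) {
    j <- rng(length(pool))
    out[i] <- pool[j]
    pool <- pool[-j]
  }
  out
}
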