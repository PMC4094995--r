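#' Verify that a gap-fill solution restores growth
#'
#' Re-solves plain FBA on the model extended with exactly the solution's
#' active candidate reactions (unpenalized, with their declared bounds) and
#' checks that the maximum biomass flux exceeds `eps_growth`. This is the
#' soundness gate every reported solution must pass.
#'
#' @param model A preprocessed `fgf_model`.
#' @param pool The `fgf_pool` the solution was drawn from.
#' @param solution An `fgf_solution`, or a character vector of candidate
#'   ids.
#' @param eps_growth Growth threshold.
#' @return `TRUE` iff the extended model grows.
#' @export
verify_solution <- function(model, pool, solution,
                            eps_growth = fgf_tol$eps_growth) {
  ids <- if (inherits(solution, "fgf_solution")) solution$active_set
         else as.character(solution)
  unknown <- setdiff(ids, names(pool$candidates))
  if (length(unknown))
    stop("active_set contains ids not in the candidate pool: ",
         paste(unknown, collapse = ", "))
  sol <- fba(model, extra_reactions = pool$candidates[ids])
  isTRUE(sol$solver_status == "optimal" && sol$biomass_flux > eps_growth)
}

#' Prune non-essential low-flux reactions from a solution
#'
#' Low-flux candidates in a gap-fill solution may merely nudge the biomass
#' up rather than being essential for growth. This check drops every
#' candidate whose flux is below `flux_ratio_threshold` times the largest
#' candidate flux in the solution, re-verifies, and keeps the reduction only
#' if the smaller set still restores growth (recursively re-pruning it);
#' otherwise the original solution is returned. The returned solution
#' always passes [verify_solution()] (assuming the input did), and its
#' active set is a subset of the input's.
#'
#' @param model A preprocessed `fgf_model`.
#' @param pool The `fgf_pool` the solution was drawn from.
#' @param solution A verified `fgf_solution`.
#' @param flux_ratio_threshold Relative flux threshold (default 0.01: a
#'   candidate below 1% of the solution's top candidate flux is tentatively
#'   dropped).
#' @param eps_growth Growth threshold used for re-verification.
#' @return An `fgf_solution` (possibly the input, unchanged).
#' @export
prune_low_flux <- function(model, pool, solution,
                           flux_ratio_threshold = 0.01,
                           eps_growth = fgf_tol$eps_growth) {
  stopifnot(inherits(solution, "fgf_solution"),
            flux_ratio_threshold >= 0)
  if (!length(solution$active_set)) return(solution)
  fmax <- max(solution$candidate_fluxes)
  low <- solution$active_set[
    solution$candidate_fluxes < flux_ratio_threshold * fmax]
  if (!length(low)) return(solution)
  reduced <- setdiff(solution$active_set, low)
  if (!verify_solution(model, pool, reduced, eps_growth))
    return(solution)
  # rebuild fluxes for the reduced set by plain FBA on model + reduced
  sol <- fba(model, extra_reactions = pool$candidates[reduced])
  pruned <- structure(
    list(delta = solution$delta,
         active_set = sort(reduced),
         biomass_flux = sol$biomass_flux,
         candidate_fluxes = sol$fluxes[sort(reduced)],
         total_cost = sum(pool$costs[reduced])),
    class = "fgf_solution")
  prune_low_flux(model, pool, pruned, flux_ratio_threshold, eps_growth)
}
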