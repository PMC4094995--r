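# Minimum-cost gap-filling as a mixed-integer program.
#
# The exact formulation attaches a binary inclusion variable y_r to every
# candidate r (f_r <= bigM * y_r, so y_r = 0 forces f_r = 0), requires
# growth (f_b above the threshold) and minimizes sum(c_r * y_r). With no
# MILP solver available as a dependency, the program is solved exactly by
# branch and bound on the y_r: each node either excludes a candidate
# (its flux bound drops to zero) or includes it (its cost is committed);
# an LP maximizing the biomass over the still-allowed candidates prunes
# infeasible nodes, and the committed cost prunes nodes that cannot beat
# the incumbent. The search is exhaustive, so the returned set has provably
# minimum cost. bigM equals the package flux cap, which bounds every
# feasible flux.

#' Describe the MILP gap-filling formulation
#'
#' Returns a structural description of the exact minimum-cost formulation
#' solved by [milp_gap_fill()]: flux variables as in the LP, one binary
#' inclusion variable per candidate with big-M linking constraints, a hard
#' growth constraint on the biomass flux, and the cost-minimizing
#' objective. A soft-biomass variant (each biomass metabolite contributing
#' `biomass_gain` when producible, instead of a hard growth constraint) is
#' the documented alternative; it is not the default because the heuristic
#' it is compared against treats the full biomass as fixed.
#'
#' @param model A preprocessed `fgf_model`.
#' @param pool A preprocessed, costed `fgf_pool`.
#' @param eps_growth Growth threshold used as the hard biomass constraint.
#' @return A list describing the formulation (class `fgf_milp`).
#' @export
milp_formulation <- function(model, pool, eps_growth = fgf_tol$eps_growth) {
  structure(list(
    flux_variables = c(names(model$reactions), names(pool$candidates)),
    inclusion_variables = names(pool$candidates),
    big_m = fgf_tol$flux_cap,
    growth_constraint = paste0("f_b >= ", eps_growth),
    objective = "minimize sum(c_r * y_r)",
    linking = "f_r <= big_m * y_r for every candidate r"),
    class = "fgf_milp")
}

#' Minimum-cost gap-filling (exact oracle)
#'
#' Finds a candidate subset of provably minimum total cost whose addition
#' lets the model grow. Intended as ground truth on small instances (the
#' search is exponential in the number of connectable candidates) and as a
#' slower, exact alternative to [fast_gap_filling()].
#'
#' @param model A preprocessed `fgf_model`.
#' @param pool A preprocessed `fgf_pool`; unassigned costs are filled from
#'   `scheme`.
#' @param scheme A [cost_scheme()] used for any unassigned candidate costs.
#' @param time_limit Wall-clock budget in seconds; on expiry the best
#'   incumbent found so far is returned with status `"timeout"`.
#' @param eps_growth Growth threshold.
#' @param eps_active Flux threshold used when picking branching candidates.
#' @return An `fgf_solution` with attribute `status` one of `"optimal"` or
#'   `"timeout"` (best found, not proven optimal). When no candidate subset
#'   restores growth (or none was found in time), an empty `fgf_solution`
#'   with `status` `"infeasible"` (respectively `"timeout"`).
#' @export
milp_gap_fill <- function(model, pool, scheme = default_cost_scheme(),
                          time_limit = Inf,
                          eps_growth = fgf_tol$eps_growth,
                          eps_active = fgf_tol$eps_active) {
  if (anyNA(pool$costs)) pool <- assign_costs(pool, scheme)
  M <- names(pool$candidates)
  t0 <- proc.time()[["elapsed"]]
  timed_out <- FALSE

  # max biomass with `allowed` candidates attached, slightly biased against
  # needless candidate flux so the active set identifies needed candidates
  relax <- function(allowed, included) {
    cand <- pool$candidates[allowed]
    m2 <- model
    m2$reactions <- c(m2$reactions, cand)
    lp <- build_lp(m2, pool = NULL)
    cost <- lp$cost
    free <- setdiff(allowed, included)
    cost[free] <- 1e-6 * pool$costs[free]
    lp$cost <- cost
    solve_at(lp, delta = 1)
  }

  incumbent <- NULL
  incumbent_cost <- Inf

  # DFS over (include, exclude); include-first to find feasible sets early
  stack <- list(list(inc = character(0), exc = character(0)))
  while (length(stack)) {
    if (proc.time()[["elapsed"]] - t0 > time_limit) { timed_out <- TRUE; break }
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lb <- sum(pool$costs[node$inc])
    if (lb >= incumbent_cost) next
    allowed <- setdiff(M, node$exc)
    sol <- relax(allowed, node$inc)
    if (sol$solver_status != "optimal" || sol$biomass_flux <= eps_growth)
      next # no growth even with every allowed candidate: prune
    free <- setdiff(allowed, node$inc)
    free_active <- free[abs(sol$fluxes[free]) > eps_active]
    if (!length(free_active)) {
      # the relaxation grows using (essentially) only the included set;
      # confirm by re-solve before accepting as incumbent
      chk <- fba(model, extra_reactions = pool$candidates[node$inc])
      if (chk$solver_status == "optimal" && chk$biomass_flux > eps_growth) {
        if (lb < incumbent_cost) {
          incumbent <- node$inc
          incumbent_cost <- lb
        }
        next
      }
      # some free candidate carries a sub-threshold but required flux
      free_active <- free[abs(sol$fluxes[free]) > 0]
      if (!length(free_active)) next
    }
    br <- free_active[which.max(abs(sol$fluxes[free_active]))]
    # exclude-branch pushed first so the include-branch is explored first
    stack[[length(stack) + 1L]] <- list(inc = node$inc,
                                        exc = c(node$exc, br))
    stack[[length(stack) + 1L]] <- list(inc = c(node$inc, br),
                                        exc = node$exc)
  }

  if (is.null(incumbent))
    return(structure(list(), class = "fgf_solution",
                     status = if (timed_out) "timeout" else "infeasible"))
  inc <- sort(incumbent)
  fsol <- fba(model, extra_reactions = pool$candidates[inc])
  out <- structure(
    list(delta = NA_real_,
         active_set = inc,
         biomass_flux = fsol$biomass_flux,
         candidate_fluxes = fsol$fluxes[inc],
         total_cost = sum(pool$costs[inc])),
    class = "fgf_solution")
  attr(out, "status") <- if (timed_out) "timeout" else "optimal"
  out
}
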