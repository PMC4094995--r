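#' Gap-fill a metabolic network by binary search on the biomass weight
#'
#' The LP-only gap-filling heuristic. One LP is built over the model
#' reactions N plus the full candidate pool M, with objective
#' `delta * f_b - sum over M of c_r * f_r`. The weight `delta` starts at
#' `|M|` (an initial probe generous enough to activate many candidates) and
#' is then binary-searched over `(0, |M|]`: whenever the LP optimum has
#' biomass flux above `eps_growth`, the set of candidates carrying flux
#' above `eps_active` is recorded as a solution and the upper bracket
#' endpoint moves down to `delta`; otherwise the lower endpoint moves up.
#' The search stops when the bracket is narrower than 1, so at most
#' `ceiling(log2(|M|)) + 1` LPs are solved (see [iteration_count()]).
#'
#' If even the initial probe at `delta = |M|` yields no growth, no set of
#' candidate reactions can produce the entire set of biomass metabolites at
#' this weighting and an empty list is returned, with a diagnostic
#' attribute recommending a reduction of the biomass reaction's metabolite
#' set.
#'
#' Recorded solutions are deduplicated by active set (keeping the fluxes of
#' the smallest-`delta` occurrence) and sorted by ascending set size, then
#' ascending total cost, then lexicographic ids. The heuristic tries to
#' reduce the number of suggested reactions but does not guarantee the
#' minimum set — see [milp_gap_fill()] for the exact (and far more
#' expensive) formulation.
#'
#' @param model A preprocessed `fgf_model` (see [preprocess_model()]).
#' @param pool A preprocessed `fgf_pool` with costs assigned; `|M| >= 1`.
#' @param eps_growth Biomass flux above which the model counts as growing.
#' @param eps_active Candidate flux above which a candidate counts as
#'   active.
#' @return A list of `fgf_solution` objects (possibly empty), each with
#'   fields `delta`, `active_set`, `biomass_flux`, `candidate_fluxes`,
#'   `total_cost`. Attributes: `lp_solves` (number of LPs solved), `trace`
#'   (a data.frame with one row per iteration: `delta`, solver status,
#'   `biomass_flux`, active-candidate count), `diagnostic` (on
#'   infeasibility), `error` (on solver failure, with the partial solution
#'   list returned).
#' @references An LP-only network completion heuristic with a parametric
#'   biomass weight; see the package vignette for the algorithm account.
#' @export
fast_gap_filling <- function(model, pool,
                             eps_growth = fgf_tol$eps_growth,
                             eps_active = fgf_tol$eps_active) {
  M <- pool_size(pool)
  if (M < 1L) stop("candidate pool is empty")
  lp <- build_lp(model, pool)
  solutions <- list()
  solves <- 0L
  trace <- list()

  record <- function(sol, delta) {
    active <- lp$candidate_ids[
      abs(sol$fluxes[lp$candidate_ids]) > eps_active]
    solutions[[length(solutions) + 1L]] <<- structure(
      list(delta = delta,
           active_set = sort(active),
           biomass_flux = sol$biomass_flux,
           candidate_fluxes = sol$fluxes[active],
           total_cost = sum(pool$costs[active])),
      class = "fgf_solution")
  }

  probe <- function(delta) {
    solves <<- solves + 1L
    sol <- solve_at(lp, delta)
    trace[[solves]] <<- data.frame(
      iteration = solves, delta = delta, status = sol$solver_status,
      biomass_flux = if (is.na(sol$biomass_flux)) NA_real_ else sol$biomass_flux,
      n_active = if (sol$solver_status == "optimal")
        sum(abs(sol$fluxes[lp$candidate_ids]) > eps_active) else NA_integer_)
    sol
  }

  # initial probe at delta = |M|
  sol <- probe(M)
  if (sol$solver_status != "optimal")
    return(structure(list(), lp_solves = solves,
                     trace = do.call(rbind, trace),
                     error = "solver error at initial probe"))
  if (is.na(sol$biomass_flux) || sol$biomass_flux <= eps_growth) {
    out <- list()
    attr(out, "lp_solves") <- solves
    attr(out, "trace") <- do.call(rbind, trace)
    attr(out, "diagnostic") <- paste(
      "no set of candidate reactions can produce the entire set of biomass",
      "metabolites; consider reducing the number of metabolites in the",
      "biomass reaction")
    return(out)
  }
  record(sol, M)

  lo <- 0; hi <- M
  while (hi - lo > 1) {
    delta <- (lo + hi) / 2
    sol <- probe(delta)
    if (sol$solver_status != "optimal") {
      out <- finalize_solutions(solutions)
      attr(out, "lp_solves") <- solves
      attr(out, "trace") <- do.call(rbind, trace)
      attr(out, "error") <- paste0("solver error at delta = ", delta)
      return(out)
    }
    if (sol$biomass_flux > eps_growth) {
      record(sol, delta)
      hi <- delta
    } else {
      lo <- delta
    }
  }
  out <- finalize_solutions(solutions)
  attr(out, "lp_solves") <- solves
  attr(out, "trace") <- do.call(rbind, trace)
  out
}

# dedup by active set (keep smallest-delta occurrence's fluxes), then sort
# by set size, total cost, lexicographic ids
finalize_solutions <- function(solutions) {
  if (!length(solutions)) return(list())
  key <- vapply(solutions, function(s) paste(s$active_set, collapse = ";"), "")
  kept <- lapply(split(seq_along(solutions), key), function(idx) {
    deltas <- vapply(solutions[idx], `[[`, 0, "delta")
    solutions[[idx[which.min(deltas)]]]
  })
  size <- vapply(kept, function(s) length(s$active_set), 0L)
  cost <- vapply(kept, function(s) s$total_cost, 0)
  ids <- vapply(kept, function(s) paste(s$active_set, collapse = ";"), "")
  out <- kept[order(size, cost, ids)]
  names(out) <- NULL
  out
}

#' Worst-case LP-solve count of the gap-filling binary search
#'
#' The bracket starts at width `pool_size` and halves until its width is at
#' most 1, after an initial probe at `delta = pool_size`; the driver
#' therefore solves at most `ceiling(log2(pool_size)) + 1` LPs.
#'
#' @param pool_size Number of candidate reactions, `>= 1`.
#' @return The worst-case number of LP solves.
#' @export
iteration_count <- function(pool_size) {
  if (!is.numeric(pool_size) || length(pool_size) != 1L || pool_size < 1)
    stop("pool_size must be a positive integer")
  as.integer(ceiling(log2(pool_size)) + 1L)
}

#' @exportS3Method base::print
print.fgf_solution <- function(x, ...) {
  cat("Gap-fill solution: |R| = ", length(x$active_set),
      ", total cost ", x$total_cost,
      ", biomass flux ", signif(x$biomass_flux, 6),
      " (found at delta = ", signif(x$delta, 6), ")\n", sep = "")
  if (length(x$active_set))
    cat("  ", paste0(x$active_set, " (flux ",
                     signif(x$candidate_fluxes, 6), ")",
                     collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Serialize gap-fill solutions
#'
#' @param solutions List of `fgf_solution` (as returned by
#'   [fast_gap_filling()]).
#' @param json Optional path for a JSON report.
#' @param tsv Optional path for a human-readable TSV (one row per solution,
#'   ids semicolon-joined).
#' @param verified Optional logical vector marking solutions that passed
#'   [verify_solution()].
#' @return The report as a list, invisibly.
#' @export
write_solutions <- function(solutions, json = NULL, tsv = NULL,
                            verified = NULL) {
  rows <- lapply(seq_along(solutions), function(i) {
    s <- solutions[[i]]
    list(delta = s$delta, active_set = as.list(s$active_set),
         biomass_flux = s$biomass_flux,
         candidate_fluxes = as.list(s$candidate_fluxes),
         total_cost = s$total_cost,
         verified = if (is.null(verified)) NA else verified[i])
  })
  report <- list(schema = "fastgapfill-solutions/1", solutions = rows)
  if (!is.null(json))
    jsonlite::write_json(report, json, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  if (!is.null(tsv)) {
    df <- data.frame(
      n_reactions = vapply(solutions, function(s) length(s$active_set), 0L),
      total_cost = vapply(solutions, function(s) s$total_cost, 0),
      biomass_flux = vapply(solutions, function(s) s$biomass_flux, 0),
      delta = vapply(solutions, function(s) s$delta, 0),
      reactions = vapply(solutions, function(s)
        paste(s$active_set, collapse = ";"), ""))
    if (!is.null(verified)) df$verified <- verified
    write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(report)
}
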