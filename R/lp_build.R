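# Steady-state LP construction and solution.
#
# Every program built here has the form
#     maximize  c'v   s.t.  S v = 0,  0 <= v <= u,
# with one flux variable per reaction of N (model, incl. biomass and
# exchanges) union M (candidates) and one mass-balance equality per
# metabolite. The objective template carries -c_r for each candidate and 0
# for model reactions; only the biomass coefficient (the search weight
# delta) changes between iterations, so the constraint matrix is built once.

# Iteratively deactivate columns that can never carry flux: a metabolite
# with no producing (or no consuming) active column forces all its
# consumers (producers) to zero. This is a pure presolve: removed fluxes
# are zero in every feasible solution, so optima are unchanged. It shrinks
# decoy-heavy candidate pools to the connected core before the simplex runs.
reduce_blocked <- function(A, ub) {
  active <- ub > 0
  P <- A > 0
  Ng <- A < 0
  tP <- Matrix::t(P)
  tN <- Matrix::t(Ng)
  repeat {
    has_prod <- as.vector(P %*% active) > 0
    has_cons <- as.vector(Ng %*% active) > 0
    bad <- (as.vector(tP %*% !has_cons) + as.vector(tN %*% !has_prod)) > 0
    newactive <- active & !bad
    if (all(newactive == active)) break
    active <- newactive
  }
  active
}

# Solve max c'x s.t. Ax = 0, 0 <= x <= ub, with the in-package bounded
# simplex. Returns list(x, objective, status, iterations, residual).
solve_lp_max <- function(A, obj, ub, tol = 1e-9, maxit = 200000L) {
  A <- as(as(A, "CsparseMatrix"), "generalMatrix")
  m <- nrow(A); n <- ncol(A)
  if (n == 0L)
    return(list(x = numeric(0), objective = 0, status = 0L, residual = 0))
  res <- simplex_bounded(m, n, A@p, A@i, A@x, as.numeric(obj),
                         as.numeric(ub), tol, as.integer(maxit))
  resid <- if (m) max(abs(as.vector(A %*% res$x))) else 0
  res$residual <- resid
  res
}

#' Build the gap-filling LP
#'
#' Assembles the steady-state LP over the model reactions N (including
#' biomass and exchanges) and the candidate pool M: one flux variable per
#' reaction, one mass-balance equality per metabolite (metabolites
#' referenced only by candidates are included, so disconnected candidates
#' are forced to zero flux). The objective template holds `-c_r` for every
#' candidate and 0 for every model reaction; the biomass coefficient is the
#' parameter supplied later to [solve_at()]. The constraint matrix is built
#' (and presolved) once and reused across all binary-search iterations.
#'
#' @param model A preprocessed `fgf_model` (irreversible reactions,
#'   environment attached; see [preprocess_model()]).
#' @param pool A preprocessed `fgf_pool` with all costs assigned, or `NULL`
#'   for a plain FBA program.
#' @return An object of class `fgf_lp` with fields `n_variables`,
#'   `n_constraints`, `var_ids`, `candidate_ids`, `biomass`, `cost`, `ub`.
#' @export
build_lp <- function(model, pool = NULL) {
  rxns <- model$reactions
  if (!is.null(pool)) {
    if (anyNA(pool$costs))
      stop("candidate pool has unassigned costs; run assign_costs() first")
    clash <- intersect(names(pool$candidates), names(rxns))
    if (length(clash))
      stop("candidate ids collide with model reaction ids: ",
           paste(clash, collapse = ", "))
    all_rxns <- c(rxns, pool$candidates)
  } else {
    all_rxns <- rxns
  }
  rev_ <- vapply(all_rxns, `[[`, TRUE, "reversible")
  if (any(rev_))
    stop("LP requires irreversible reactions; run split_reversible()/preprocess first (offending: ",
         paste(head(names(all_rxns)[rev_], 3L), collapse = ", "), ")")
  lbs <- vapply(all_rxns, `[[`, 0, "lower_bound")
  if (any(lbs < 0))
    stop("negative lower bound after preprocessing")
  if (any(lbs > 0))
    stop("strictly positive flux lower bounds are not supported")
  if (!model$biomass %in% names(rxns))
    stop("biomass reaction '", model$biomass, "' not in model")

  met_ids <- unique(c(names(model$metabolites),
                      unlist(lapply(all_rxns, function(r) names(r$stoichiometry)))))
  met_idx <- setNames(seq_along(met_ids), met_ids)
  nnz <- sum(vapply(all_rxns, function(r) length(r$stoichiometry), 0L))
  ri <- integer(nnz); ci <- integer(nnz); xv <- numeric(nnz)
  k <- 0L
  for (j in seq_along(all_rxns)) {
    st <- all_rxns[[j]]$stoichiometry
    ln <- length(st)
    if (!ln) next
    idx <- k + seq_len(ln)
    ri[idx] <- met_idx[names(st)]
    ci[idx] <- j
    xv[idx] <- st
    k <- k + ln
  }
  A <- Matrix::sparseMatrix(i = ri[seq_len(k)], j = ci[seq_len(k)],
                            x = xv[seq_len(k)],
                            dims = c(length(met_ids), length(all_rxns)),
                            dimnames = list(met_ids, names(all_rxns)))
  ub <- pmin(vapply(all_rxns, `[[`, 0, "upper_bound"), fgf_tol$flux_cap)
  cost <- setNames(numeric(length(all_rxns)), names(all_rxns))
  cand_ids <- character(0)
  if (!is.null(pool)) {
    cand_ids <- names(pool$candidates)
    cost[cand_ids] <- pool$costs[cand_ids]
  }
  keep <- reduce_blocked(A, ub)
  row_keep <- as.vector((abs(A) %*% keep) > 0)
  lp <- list(A = A, ub = ub, cost = cost,
             var_ids = names(all_rxns),
             candidate_ids = cand_ids,
             biomass = model$biomass,
             n_variables = length(all_rxns),
             n_constraints = length(met_ids),
             keep = keep, row_keep = row_keep,
             A_red = A[row_keep, keep, drop = FALSE],
             ub_red = ub[keep])
  class(lp) <- "fgf_lp"
  lp
}

#' Solve the gap-filling LP at a given biomass weight
#'
#' Maximizes `delta * f_b - sum(c_r * f_r)` over the steady-state polytope
#' of the LP template. Solver failures are reported through
#' `solver_status`, never raised.
#'
#' @param lp An `fgf_lp` from [build_lp()].
#' @param delta Non-negative weight on the biomass flux.
#' @return An object of class `fgf_flux` with fields `fluxes` (named, full
#'   length, zeros for presolved-out reactions), `biomass_flux`,
#'   `objective_value`, `solver_status` (`"optimal"` or `"error"`).
#' @export
solve_at <- function(lp, delta) {
  stopifnot(inherits(lp, "fgf_lp"), delta >= 0)
  obj <- -lp$cost
  obj[lp$biomass] <- delta
  fluxes <- setNames(numeric(lp$n_variables), lp$var_ids)
  if (!any(lp$keep) || !lp$keep[[lp$biomass]] && all(obj[lp$keep] <= 0)) {
    # nothing can improve on the zero flux vector
    return(structure(list(fluxes = fluxes, biomass_flux = 0,
                          objective_value = 0, solver_status = "optimal"),
                     class = "fgf_flux"))
  }
  res <- tryCatch(
    solve_lp_max(lp$A_red, obj[lp$keep], lp$ub_red),
    error = function(e) NULL)
  if (is.null(res) || res$status != 0L ||
      res$residual > fgf_tol$eps_balance * max(1, max(abs(res$x))))
    return(structure(list(fluxes = fluxes, biomass_flux = NA_real_,
                          objective_value = NA_real_,
                          solver_status = "error"),
                     class = "fgf_flux"))
  x <- res$x
  x[abs(x) < 1e-11] <- 0
  fluxes[lp$keep] <- x
  structure(list(fluxes = fluxes,
                 biomass_flux = unname(fluxes[lp$biomass]),
                 objective_value = res$objective,
                 solver_status = "optimal"),
            class = "fgf_flux")
}

#' Flux balance analysis (maximize biomass)
#'
#' Builds and solves the plain FBA program for a preprocessed model,
#' optionally extended with extra (unpenalized) reactions — typically a
#' candidate set under evaluation.
#'
#' @param model A preprocessed `fgf_model`.
#' @param extra_reactions Optional named list of irreversible [reaction()]s
#'   added to the network without penalty.
#' @return An `fgf_flux` whose `biomass_flux` is the model's maximum growth.
#' @export
fba <- function(model, extra_reactions = NULL) {
  if (length(extra_reactions)) {
    names(extra_reactions) <- vapply(extra_reactions, `[[`, "", "id")
    model$reactions <- c(model$reactions, extra_reactions)
  }
  # with no pool the cost template is all-zero, so delta = 1 maximizes f_b
  solve_at(build_lp(model, pool = NULL), delta = 1)
}

#' Export an LP in CPLEX-LP text format (debugging aid)
#'
#' @param lp An `fgf_lp`.
#' @param delta Biomass weight for the objective.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_lp_cplex <- function(lp, delta, path) {
  obj <- -lp$cost
  obj[lp$biomass] <- delta
  con <- file(path, "w")
  on.exit(close(con))
  terms <- sprintf("%+g %s", obj[obj != 0], lp$var_ids[obj != 0])
  writeLines(c("Maximize", paste(" obj:", paste(terms, collapse = " "))), con)
  writeLines("Subject To", con)
  At <- Matrix::t(lp$A)
  for (i in seq_len(lp$n_constraints)) {
    col <- At[, i]
    nz <- which(col != 0)
    if (!length(nz)) next
    writeLines(paste0(" m", i, ": ",
                      paste(sprintf("%+g %s", col[nz], lp$var_ids[nz]),
                            collapse = " "), " = 0"), con)
  }
  writeLines("Bounds", con)
  writeLines(sprintf(" 0 <= %s <= %g", lp$var_ids, lp$ub), con)
  writeLines("End", con)
  invisible(path)
}
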