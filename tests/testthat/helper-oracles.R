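# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: LP optima come from boot::simplex (a separate dense
# simplex implementation), free-sign FBA uses variable shifting instead of
# reaction splitting, and minimum-cost completions come from exhaustive
# subset enumeration.

# max c'x s.t. A x = 0, 0 <= x <= u, via boot::simplex
oracle_lp_max <- function(A, cvec, u) {
  A <- as.matrix(A)
  res <- tryCatch(
    boot::simplex(a = cvec,
                  A1 = diag(length(cvec)), b1 = u,
                  A3 = A, b3 = rep(0, nrow(A)),
                  maxi = TRUE, n.iter = 10000),
    error = function(e) NULL) # boot's tableau can break down on degeneracy
  if (is.null(res) || res$solved != 1)
    return(list(objective = NA_real_, x = NULL, solved = FALSE))
  list(objective = unname(res$value), x = as.numeric(res$soln),
       solved = TRUE)
}

# max biomass over S v = 0, lb <= v <= ub with free-sign reversible fluxes,
# by shifting w = v - lb (w >= 0), never by splitting reactions
oracle_fba_freesign <- function(model) {
  rxns <- model$reactions
  mets <- unique(unlist(lapply(rxns, function(r) names(r$stoichiometry))))
  S <- matrix(0, length(mets), length(rxns),
              dimnames = list(mets, names(rxns)))
  for (j in seq_along(rxns))
    S[names(rxns[[j]]$stoichiometry), j] <- rxns[[j]]$stoichiometry
  lb <- vapply(rxns, `[[`, 0, "lower_bound")
  ub <- pmin(vapply(rxns, `[[`, 0, "upper_bound"), 1e6)
  lb <- pmax(lb, -1e6)
  cvec <- as.numeric(names(rxns) == model$biomass)
  # v = w + lb:  S w = -S lb,  0 <= w <= ub - lb
  b3 <- as.numeric(-S %*% lb)
  # boot::simplex wants b >= 0 on equality rows; flip signs where needed
  flip <- b3 < 0
  A3 <- S; A3[flip, ] <- -A3[flip, ]; b3[flip] <- -b3[flip]
  res <- boot::simplex(a = cvec, A1 = diag(length(cvec)), b1 = ub - lb,
                       A3 = A3, b3 = b3, maxi = TRUE, n.iter = 10000)
  stopifnot(res$solved == 1)
  v <- as.numeric(res$soln) + lb
  list(biomass_flux = unname(v[which(names(rxns) == model$biomass)]),
       fluxes = v)
}

# exact minimum-cost completion by cost-ordered exhaustive enumeration of
# all candidate subsets (first growing subset in ascending cost order)
oracle_min_cost_completion <- function(model, pool,
                                       eps_growth = 1e-6) {
  ids <- names(pool$candidates)
  k <- length(ids)
  stopifnot(k <= 16) # exhaustive
  subsets <- lapply(0:(2^k - 1), function(mask)
    ids[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0])
  costs <- vapply(subsets, function(s) sum(pool$costs[s]), 0)
  ord <- order(costs, vapply(subsets, length, 0L))
  for (i in ord) {
    s <- subsets[[i]]
    sol <- fba(model, extra_reactions = pool$candidates[s])
    if (sol$solver_status == "optimal" && sol$biomass_flux > eps_growth)
      return(list(set = sort(s), cost = costs[i]))
  }
  NULL
}

# random connected toy model with a mix of reversible reactions, used for
# solver and split-equivalence property tests
random_toy_model <- function(seed, n_mets = 5, p_rev = 0.4) {
  set.seed(seed)
  mets <- paste0("M", seq_len(n_mets))
  rxns <- list()
  for (i in seq_len(n_mets - 1)) {
    id <- paste0("T", i)
    rev <- runif(1) < p_rev
    rxns[[id]] <- reaction(id,
      setNames(c(-1, sample(1:2, 1)), mets[c(i, i + 1)]),
      reversible = rev,
      lower_bound = if (rev) -sample(2:8, 1) else 0,
      upper_bound = sample(5:15, 1),
      kind = "enzymatic", taxonomic_status = "in_range")
  }
  # one random cross edge to create a branch
  ij <- sample(n_mets, 2)
  rev2 <- runif(1) < p_rev
  rxns[["X1"]] <- reaction("X1",
    setNames(c(-1, 1), mets[ij]), reversible = rev2,
    lower_bound = if (rev2) -sample(1:5, 1) else 0,
    upper_bound = sample(5:15, 1))
  rxns[["BIOMASS"]] <- reaction("BIOMASS", setNames(-1, mets[n_mets]),
                                kind = "biomass")
  metabolic_model(lapply(mets, metabolite), rxns, biomass = "BIOMASS",
                  nutrients = setNames(sample(5:15, 1), mets[1]))
}
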