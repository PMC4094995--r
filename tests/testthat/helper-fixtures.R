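# Shared benchmark fixtures, built in code at test time.

# T1: 3-metabolite chain with the terminal biosynthesis step knocked out
# and two dead-end decoys (|M| = 3). The knocked-out reaction is the unique
# minimum-cost completion. Seed 1 gives the terminal step a biomass yield
# of 2 per unit flux, so re-adding it (cost 5) is profitable for any
# delta > 2.5 — inside the search range (0, |M| = 3].
t1_instance <- function() {
  complete <- make_chain_model(3, 1, seed = 1)
  ko <- knockout(complete, "B1")
  pool <- add_decoys(ko$pool, ko$model, 2, seed = 1)
  pool <- assign_costs(pool)
  list(complete = complete, model = ko$model, pool = pool,
       knocked_out = "B1")
}

# T2: longer chain, 4 knockouts, decoy-padded to |M| = 34; the knocked-out
# set is the unique minimal completion (every chain/branch step is
# essential). The pool must be comfortably larger than the completion's
# total cost for the initial probe at delta = |M| to be generous enough —
# the regime the method targets, where |M| is a reaction database several
# orders larger than any one completion.
t2_instance <- function() {
  make_instance(n_metabolites = 10, biomass_size = 2, n_knockouts = 4,
                n_decoys = 30, seed = 11)
}

# T3: one gap, fillable by either a direct (costlier per unit) reaction or
# a cheaper but capacity-limited two-step path; padded to |M| = 16.
# Designed so the binary search records sets of two different sizes.
t3_instance <- function() {
  mets <- c("A", "B", "X", "Z")
  model <- metabolic_model(
    lapply(mets, metabolite),
    list(reaction("R1", c(A = -1, B = 1), kind = "enzymatic",
                  taxonomic_status = "in_range"),
         reaction("BIOMASS", c(Z = -1), kind = "biomass")),
    biomass = "BIOMASS", nutrients = c(A = 10))
  model <- preprocess_model(model)
  cands <- list(
    reaction("RC1", c(B = -1, Z = 1), kind = "enzymatic",
             taxonomic_status = "in_range"),
    reaction("RCa", c(B = -1, X = 1), upper_bound = 5),
    reaction("RCb", c(X = -1, Z = 1)))
  costs <- c(5, 1.2, 1.2)
  pool <- candidate_pool(cands, costs)
  pool <- add_decoys(pool, model, 13, seed = 3)
  pool <- assign_costs(pool)
  list(model = model, pool = pool)
}

# Heuristic-gap exhibit: a trace nutrient E (uptake cap 0.001) lets a
# second candidate add a sliver of biomass, so the binary search always
# records it alongside the essential candidate; the exact minimum is the
# essential candidate alone, and low-flux pruning removes the extra one.
gap_exhibit_instance <- function() {
  mets <- c("A", "B", "C", "E")
  model <- metabolic_model(
    lapply(mets, metabolite),
    list(reaction("R1", c(A = -1, B = 1), kind = "enzymatic",
                  taxonomic_status = "in_range"),
         reaction("BIOMASS", c(C = -1), kind = "biomass")),
    biomass = "BIOMASS", nutrients = c(A = 10, E = 0.001))
  model <- preprocess_model(model)
  pool <- candidate_pool(
    list(reaction("RC1", c(B = -1, C = 1)),
         reaction("RC2", c(E = -1, C = 1))),
    costs = c(2.2, 2.6))
  pool <- add_decoys(pool, model, 6, seed = 7)
  pool <- assign_costs(pool)
  list(model = model, pool = pool)
}

# Model-1 analogue: a working chain whose terminal biosynthesis step is
# removed; the candidate pool offers that reaction in reversible form, so
# the filler must pick the correct direction from the split pair.
terminal_knockout_instance <- function() {
  complete <- make_chain_model(4, 1, seed = 2)
  ko <- knockout(complete, "B1")
  b1 <- complete$reactions[["B1"]]
  revcand <- reaction("CAND_B1", b1$stoichiometry, reversible = TRUE,
                      lower_bound = -b1$upper_bound,
                      upper_bound = b1$upper_bound,
                      kind = "enzymatic", taxonomic_status = "in_range")
  pool <- candidate_pool(list(revcand))
  pool <- add_decoys(pool, ko$model, 4, seed = 5)
  pool <- preprocess_pool(pool)
  pool <- assign_costs(pool)
  list(complete = complete, model = ko$model, pool = pool)
}
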