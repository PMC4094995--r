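test_that("a complete model yields one solution with an empty active set", {
  model <- preprocess_model(metabolic_model(
    lapply(c("A", "B"), metabolite),
    list(reaction("R1", c(A = -1, B = 1)),
         reaction("BIOMASS", c(B = -1), kind = "biomass")),
    biomass = "BIOMASS", nutrients = c(A = 10)))
  pool <- assign_costs(candidate_pool(
    list(reaction("RC1", c(A = -1, B = 1), taxonomic_status = "in_range"),
         reaction("RC2", c(B = -1, A = 1), taxonomic_status = "in_range"))))
  sols <- fast_gap_filling(model, pool)
  expect_gte(length(sols), 1L)
  expect_identical(sols[[1]]$active_set, character(0))
  expect_equal(sols[[1]]$total_cost, 0)
  expect_gt(sols[[1]]$biomass_flux, 1e-6)
})

test_that("T1: the knocked-out reaction is recovered within the iteration budget", {
  t1 <- t1_instance()
  sols <- fast_gap_filling(t1$model, t1$pool)
  expect_gte(length(sols), 1L)
  expect_identical(sols[[1]]$active_set, "B1")
  expect_lte(attr(sols, "lp_solves"), iteration_count(pool_size(t1$pool)))
  expect_equal(iteration_count(3), 3)
})

test_that("an unproducible biomass metabolite yields no solutions plus advice", {
  model <- preprocess_model(metabolic_model(
    lapply(c("A", "B", "Z"), metabolite),
    list(reaction("R1", c(A = -1, B = 1)),
         reaction("BIOMASS", c(B = -1, Z = -1), kind = "biomass")),
    biomass = "BIOMASS", nutrients = c(A = 10)))
  pool <- assign_costs(candidate_pool( # nothing produces Z
    list(reaction("RC1", c(A = -1, B = 2), taxonomic_status = "in_range"))))
  sols <- fast_gap_filling(model, pool)
  expect_length(sols, 0L)
  expect_match(attr(sols, "diagnostic"), "reducing the number of metabolites")
})

test_that("alternative completions are reported smallest-first", {
  t3 <- t3_instance()
  sols <- fast_gap_filling(t3$model, t3$pool)
  sizes <- vapply(sols, function(s) length(s$active_set), 0L)
  expect_gte(length(sols), 2L) # several solution sets of different sizes
  expect_identical(sizes, sort(sizes))
  expect_identical(sols[[1]]$active_set, c("RCa", "RCb"))
  expect_true(all(c("RC1", "RCa", "RCb") %in% sols[[2]]$active_set))
})

test_that("the worst-case LP-solve count follows the bracket-halving recursion", {
  expect_identical(iteration_count(1), 1L)
  expect_identical(iteration_count(3), 3L)
  expect_identical(iteration_count(4096), 13L)
  expect_error(iteration_count(0), "positive")
  # oracle: simulate the bracket halving explicitly
  simulated <- function(M) {
    n <- 1L; lo <- 0; hi <- M
    while (hi - lo > 1) { hi <- (lo + hi) / 2; n <- n + 1L } # worst case
    n
  }
  for (M in c(1, 2, 3, 5, 17, 100, 1024, 5000))
    expect_identical(iteration_count(M), simulated(M))
})

test_that("observed LP-solve counts never exceed the bound", {
  for (seed in c(1, 2, 3)) {
    inst <- make_instance(n_metabolites = 9, n_knockouts = 1 + seed,
                          n_decoys = c(10, 200, 1500)[seed], seed = seed)
    sols <- fast_gap_filling(inst$model, inst$pool)
    expect_lte(attr(sols, "lp_solves"),
               iteration_count(pool_size(inst$pool)))
    expect_gte(length(sols), 1L)
  }
})

test_that("gap-filling is deterministic", {
  inst <- make_instance(n_metabolites = 8, n_knockouts = 2, n_decoys = 30,
                        seed = 13)
  a <- fast_gap_filling(inst$model, inst$pool)
  b <- fast_gap_filling(inst$model, inst$pool)
  expect_identical(a, b)
})

test_that("recorded solutions carry consistent cost and flux bookkeeping", {
  t2 <- t2_instance()
  sols <- fast_gap_filling(t2$model, t2$pool)
  for (s in sols) {
    expect_true(all(s$active_set %in% names(t2$pool$candidates)))
    expect_equal(s$total_cost, sum(t2$pool$costs[s$active_set]))
    expect_identical(sort(names(s$candidate_fluxes)), s$active_set)
    expect_true(all(s$candidate_fluxes > 0))
    expect_gt(s$biomass_flux, 1e-6)
  }
})
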