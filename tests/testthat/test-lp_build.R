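toy_setup <- function() {
  model <- metabolic_model(
    lapply(c("A", "B", "C"), metabolite),
    list(reaction("R1", c(A = -1, B = 1)),
         reaction("R2", c(B = -1, C = 1)),
         reaction("R3", c(A = -1, C = 1)),
         reaction("BIOMASS", c(C = -1), kind = "biomass")),
    biomass = "BIOMASS", nutrients = c(A = 10))
  preprocess_model(model)
}

test_that("the LP has one variable per reaction and one equality per metabolite", {
  model <- toy_setup() # 4 model reactions + 1 uptake exchange
  pool <- assign_costs(candidate_pool(
    list(reaction("RC1", c(A = -1, B = 2), taxonomic_status = "in_range"),
         reaction("RC2", c(C = -1, B = 1), taxonomic_status = "unknown"))))
  lp <- build_lp(model, pool)
  expect_equal(lp$n_variables, 7L)
  expect_equal(lp$n_constraints, 3L)
  expect_setequal(lp$candidate_ids, c("RC1", "RC2"))
  expect_equal(unname(lp$cost[c("R1", "RC1", "RC2")]), c(0, 5, 10))
})

test_that("with an empty pool and delta = 1 the LP reduces to plain FBA", {
  model <- toy_setup()
  lp <- build_lp(model, pool = NULL)
  sol <- solve_at(lp, 1)
  expect_equal(sol$biomass_flux, fba(model)$biomass_flux)
  expect_equal(sol$biomass_flux, 10) # uptake cap is the only bottleneck
})

test_that("disconnected candidates never carry flux", {
  model <- toy_setup()
  pool <- assign_costs(candidate_pool(
    list(reaction("RC1", c(Q1 = -1, Q2 = 1), taxonomic_status = "in_range"),
         reaction("RC2", c(Q3 = -1, Q4 = 2), kind = "spontaneous"))))
  lp <- build_lp(model, pool)
  sol <- solve_at(lp, 2)
  expect_equal(unname(sol$fluxes[c("RC1", "RC2")]), c(0, 0))
  expect_gt(sol$biomass_flux, 0)
})

test_that("at delta = 0 the optimum is exactly zero with all candidates inactive", {
  t1 <- t1_instance()
  lp <- build_lp(t1$model, t1$pool)
  sol <- solve_at(lp, 0)
  expect_equal(sol$objective_value, 0, tolerance = 1e-10)
  expect_true(all(sol$fluxes[lp$candidate_ids] <= 1e-10))
})

test_that("on a complete model candidates stay inactive even at delta = |M|", {
  model <- toy_setup()
  pool <- assign_costs(candidate_pool(
    list(reaction("RC1", c(A = -1, C = 1), taxonomic_status = "in_range"),
         reaction("RC2", c(B = -1, A = 1), taxonomic_status = "in_range"))))
  lp <- build_lp(model, pool)
  sol <- solve_at(lp, pool_size(pool))
  expect_equal(sol$biomass_flux, fba(model)$biomass_flux)
  expect_true(all(sol$fluxes[lp$candidate_ids] <= 1e-9))
})

test_that("on the incomplete T1 instance the knocked-out reaction activates", {
  t1 <- t1_instance()
  # brute force confirms the knocked-out reaction is the unique min completion
  ref <- oracle_min_cost_completion(t1$model, t1$pool)
  expect_identical(ref$set, "B1")
  sol <- solve_at(build_lp(t1$model, t1$pool), 3)
  expect_gt(sol$biomass_flux, 1e-6)
  expect_gt(sol$fluxes[["B1"]], 1e-8)
})

test_that("optimal biomass flux is non-decreasing in delta", {
  for (seed in c(2, 9)) {
    inst <- make_instance(n_metabolites = 7, n_knockouts = 2, n_decoys = 6,
                          seed = seed)
    lp <- build_lp(inst$model, inst$pool)
    fb <- vapply(c(0, 1, 2, 4, 8), function(d) solve_at(lp, d)$biomass_flux, 0)
    expect_true(all(diff(fb) >= -1e-9))
  }
})

test_that("the reusable template matches a freshly built LP at the same delta", {
  inst <- make_instance(n_metabolites = 6, n_knockouts = 1, n_decoys = 4,
                        seed = 4)
  lp <- build_lp(inst$model, inst$pool)
  a <- solve_at(lp, 3.5)
  b <- solve_at(build_lp(inst$model, inst$pool), 3.5)
  expect_equal(a$objective_value, b$objective_value, tolerance = 1e-6)
  expect_equal(a$fluxes, b$fluxes, tolerance = 1e-6)
})

test_that("steady state holds at every optimum", {
  inst <- make_instance(n_metabolites = 8, n_knockouts = 3, n_decoys = 10,
                        seed = 6)
  lp <- build_lp(inst$model, inst$pool)
  for (d in c(0.5, 2, 7)) {
    sol <- solve_at(lp, d)
    resid <- as.vector(lp$A %*% sol$fluxes)
    expect_lt(max(abs(resid)), 1e-6)
    expect_true(all(sol$fluxes >= -1e-9))
    expect_true(all(sol$fluxes <= lp$ub + 1e-9))
  }
})

test_that("unassigned candidate costs are rejected at build time", {
  t1 <- t1_instance()
  raw <- candidate_pool(unname(t1$pool$candidates)) # costs reset to NA
  expect_error(build_lp(t1$model, raw), "assign_costs")
})
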