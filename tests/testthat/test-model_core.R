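toy_model <- function() {
  metabolic_model(
    lapply(c("A", "B", "C"), metabolite),
    list(reaction("R1", c(A = -1, B = 1)),
         reaction("R2", c(B = -1, C = 1)),
         reaction("BIOMASS", c(C = -1), kind = "biomass")),
    biomass = "BIOMASS", nutrients = c(A = 10))
}

test_that("a well-formed model validates cleanly", {
  expect_identical(validate_model(toy_model()), character(0))
})

test_that("validate_model reports one diagnostic per violated invariant", {
  m <- toy_model()
  m$reactions[["BIOMASS"]]$stoichiometry <- c(C = 1) # produces, consumes nothing
  expect_match(validate_model(m), "empty biomass", all = FALSE)

  m2 <- toy_model()
  m2$reactions[["R2"]]$stoichiometry <- c(B = -1, X9 = 1)
  diags <- validate_model(m2)
  expect_length(diags, 1L)
  expect_match(diags, "X9")

  m3 <- toy_model()
  m3$reactions[["R1"]]$lower_bound <- -2
  expect_match(validate_model(m3), "negative lower bound", all = FALSE)

  m4 <- toy_model()
  m4$nutrients <- c(A = 10, Q = 1)
  expect_match(validate_model(m4), "nutrient.*Q", all = FALSE)
})

test_that("reaction constructor enforces its contracts", {
  expect_error(reaction("r", numeric(0)), "exchange")
  expect_silent(reaction("ex", numeric(0), kind = "exchange"))
  expect_error(reaction("r", c(A = -1), lower_bound = 5, upper_bound = 1))
  expect_error(reaction("r", c(A = -1), kind = "nonsense"))
  # zero coefficients are dropped
  r <- reaction("r", c(A = -1, B = 0, C = 2))
  expect_named(r$stoichiometry, c("A", "C"))
})

test_that("candidate pools reject duplicate ids and negative costs", {
  r1 <- reaction("RC1", c(A = -1, B = 1))
  expect_error(candidate_pool(list(r1, r1)), "duplicate")
  expect_error(candidate_pool(list(r1), costs = -1), "non-negative")
  p <- candidate_pool(list(r1), costs = NA_real_)
  expect_identical(pool_size(p), 1L)
})

test_that("pool validation flags id collisions and duplicated stoichiometry", {
  m <- toy_model()
  clash <- candidate_pool(list(reaction("R1", c(A = -1, C = 1))))
  expect_match(validate_pool(clash, m), "collides", all = FALSE)
  dupe <- candidate_pool(list(reaction("RC_dup", c(B = -1, C = 1))))
  expect_match(validate_pool(dupe, m), "duplicates stoichiometry", all = FALSE)
  expect_identical(validate_pool(candidate_pool(list(
    reaction("RCX", c(C = -1, A = 1)))), m), character(0))
})

test_that("models survive a serialize/parse round trip structurally intact", {
  for (seed in c(1, 7, 23)) {
    m <- random_toy_model(seed)
    path <- withr::local_tempfile(fileext = ".json")
    write_model(m, path)
    m2 <- read_model(path)
    expect_setequal(names(m2$metabolites), names(m$metabolites))
    expect_setequal(names(m2$reactions), names(m$reactions))
    for (id in names(m$reactions)) {
      r <- m$reactions[[id]]; r2 <- m2$reactions[[id]]
      expect_equal(sort(names(r2$stoichiometry)), sort(names(r$stoichiometry)))
      expect_equal(r2$stoichiometry[names(r$stoichiometry)], r$stoichiometry)
      expect_equal(r2$lower_bound, r$lower_bound)
      expect_equal(r2$upper_bound, r$upper_bound)
      expect_identical(r2$reversible, r$reversible)
      expect_identical(r2$kind, r$kind)
    }
    expect_equal(m2$nutrients, m$nutrients)
    expect_identical(m2$biomass, m$biomass)
  }
})

test_that("pools round trip with explicit and unassigned costs", {
  p <- candidate_pool(
    list(reaction("RC1", c(A = -1, B = 1), kind = "spontaneous"),
         reaction("RC2", c(B = -1, A = 1), reversible = TRUE,
                  lower_bound = -4, upper_bound = 9)),
    costs = c(2.5, NA))
  path <- withr::local_tempfile(fileext = ".json")
  write_pool(p, path)
  p2 <- read_pool(path)
  expect_equal(p2$costs, p$costs)
  expect_equal(p2$candidates$RC2$lower_bound, -4)
  expect_true(p2$candidates$RC2$reversible)
})
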