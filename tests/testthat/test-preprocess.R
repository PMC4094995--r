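test_that("splitting passes irreversible reactions through unchanged", {
  r <- reaction("R1", c(A = -1, B = 1), lower_bound = 0, upper_bound = 10)
  out <- split_reversible(list(r))
  expect_length(out, 1L)
  expect_equal(out[["R1"]]$stoichiometry, r$stoichiometry)
  expect_equal(out[["R1"]]$upper_bound, 10)
})

test_that("splitting a reversible reaction yields the two directed halves", {
  r <- reaction("R1", c(A = -1, B = 1), reversible = TRUE,
                lower_bound = -5, upper_bound = 10)
  out <- split_reversible(list(r))
  expect_setequal(names(out), c("R1_fwd", "R1_rev"))
  expect_equal(out$R1_fwd$stoichiometry, c(A = -1, B = 1))
  expect_equal(out$R1_fwd$upper_bound, 10)
  expect_equal(out$R1_rev$stoichiometry, c(A = 1, B = -1))
  expect_equal(out$R1_rev$upper_bound, 5)
  expect_false(any(vapply(out, `[[`, TRUE, "reversible")))
  expect_true(all(vapply(out, `[[`, 0, "lower_bound") >= 0))
})

test_that("derived split ids that collide with existing ids are an error", {
  rxns <- list(reaction("R1", c(A = -1, B = 1), reversible = TRUE,
                        lower_bound = -1),
               reaction("R1_fwd", c(A = -1, B = 1)))
  expect_error(split_reversible(rxns), "R1_fwd")
})

test_that("splitting a pool gives each direction the full parent cost", {
  p <- candidate_pool(
    lapply(1:3, function(i)
      reaction(paste0("RC", i), setNames(c(-1, 1), c("A", "B")[c(1, 2)]),
               reversible = TRUE, lower_bound = -5)),
    costs = c(1, 5, 15))
  out <- split_reversible(p)
  expect_identical(pool_size(out), 6L)
  expect_equal(unname(out$costs[c("RC2_fwd", "RC2_rev")]), c(5, 5))
  expect_equal(unname(out$costs[c("RC3_fwd", "RC3_rev")]), c(15, 15))
})

test_that("split models reach the same maximum biomass as the free-sign formulation", {
  for (seed in c(3, 4, 8, 15, 21)) {
    m <- random_toy_model(seed)
    m_env <- attach_environment(m)
    ref <- oracle_fba_freesign(m_env)$biomass_flux
    m_split <- m
    m_split$reactions <- split_reversible(m$reactions)
    got <- fba(attach_environment(m_split))$biomass_flux
    expect_equal(got, ref, tolerance = 1e-6)
  }
})

test_that("reactions without class references instantiate to themselves", {
  cm <- class_map(list(ClassX = c("m1", "m2")))
  r <- reaction("R1", c(A = -1, B = 1))
  out <- instantiate_generic(r, cm)
  expect_length(out, 1L)
  expect_equal(out[[1]]$stoichiometry, r$stoichiometry)
})

test_that("a single class expands to one reaction per member", {
  cm <- class_map(list(ClassX = c("m1", "m2")))
  r <- reaction("R1", c(ClassX = -1, A = -1, B = 1))
  out <- instantiate_generic(r, cm)
  expect_length(out, 2L)
  expect_setequal(names(out), c("R1__m1", "R1__m2"))
  expect_equal(out$R1__m1$stoichiometry[c("m1", "A", "B")],
               c(m1 = -1, A = -1, B = 1))
})

test_that("paired classes substitute in lockstep; unpaired take the product", {
  # 2x2 exhaustive table for the paired case: only (m1,m1p) and (m2,m2p)
  cm <- class_map(list(ClassX = c("m1", "m2"),
                       `ClassX-P` = c("m1p", "m2p")),
                  paired_with = c(`ClassX-P` = "ClassX"))
  r <- reaction("G1", c(ClassX = -1, `ClassX-P` = 1))
  out <- instantiate_generic(r, cm)
  expect_length(out, 2L)
  got <- lapply(out, function(x) sort(names(x$stoichiometry)))
  expect_setequal(vapply(got, paste, "", collapse = "+"),
                  c("m1+m1p", "m2+m2p"))

  cm2 <- class_map(list(ClassX = c("m1", "m2"), ClassY = c("y1", "y2")))
  r2 <- reaction("G2", c(ClassX = -1, ClassY = 1))
  expect_length(instantiate_generic(r2, cm2), 4L) # full Cartesian product
})

test_that("a class with no members drops the reaction with a warning diagnostic", {
  cm <- class_map(list(ClassX = character(0)))
  out <- instantiate_generic(reaction("G", c(ClassX = -1, B = 1)), cm)
  expect_length(out, 0L)
  expect_match(attr(out, "warning"), "no members")
})

test_that("environment attachment creates capped uptakes and is idempotent", {
  m <- metabolic_model(
    lapply(c("glucose", "B"), metabolite),
    list(reaction("R1", c(glucose = -1, B = 1)),
         reaction("BIOMASS", c(B = -1), kind = "biomass")),
    biomass = "BIOMASS", nutrients = c(glucose = 16),
    secretions = "B")
  m1 <- attach_environment(m)
  expect_equal(m1$reactions$EX_glucose_in$upper_bound, 16)
  expect_equal(m1$reactions$EX_glucose_in$stoichiometry, c(glucose = 1))
  expect_equal(m1$reactions$EX_B_out$stoichiometry, c(B = -1))
  m2 <- attach_environment(m1)
  expect_identical(names(m2$reactions), names(m1$reactions))

  # yeast-style cap
  m$nutrients <- c(glucose = 12)
  expect_equal(attach_environment(m)$reactions$EX_glucose_in$upper_bound, 12)
})

test_that("attaching an unknown nutrient is an error; empty environment means no growth", {
  m <- metabolic_model(
    lapply(c("A", "B"), metabolite),
    list(reaction("R1", c(A = -1, B = 1)),
         reaction("BIOMASS", c(B = -1), kind = "biomass")),
    biomass = "BIOMASS", nutrients = c(A = 5))
  m_bad <- m; m_bad$nutrients <- c(Z = 1)
  expect_error(attach_environment(m_bad), "Z")

  m_iso <- m; m_iso$nutrients <- numeric(0)
  m_iso <- preprocess_model(m_iso)
  expect_false(any(grepl("^EX_", names(m_iso$reactions))))
  expect_equal(fba(m_iso)$biomass_flux, 0, tolerance = 1e-9)
})
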