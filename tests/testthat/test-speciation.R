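test_that("pure water is neutral", {
  s <- speciate(aqueous_solution(temperature = 298.15))
  expect_equal(s$pH, 7.00, tolerance = 0.01)
  expect_lt(abs(s$charge_imbalance), 1e-12)
})

test_that("activity = gamma x molality for every species", {
  s <- speciate(aqueous_solution(dic = 5e-3, ca = 2e-3, na = 1e-3,
                                 cl = 1e-3, sulfide = 1e-4,
                                 temperature = 309.15))
  sp <- tidy(s)
  not_h <- !sp$species %in% c("H+", "OH-")   # pH is activity-scale
  expect_equal(sp$activity[not_h], (sp$gamma * sp$molality)[not_h],
               tolerance = 1e-12)
})

test_that("speciation matches the brute-force grid-search oracle", {
  withr::with_seed(42, {
    for (i in 1:20) {
      sol <- random_small_solution()
      ours <- speciate(sol, ion_pairs = FALSE)$pH
      ref <- oracle_speciation_ph(solution_totals(sol),
                                  attr(sol, "temperature"))
      expect_equal(ours, ref, tolerance = 1.1e-3)
    }
  })
})

test_that("speciation is idempotent on its own totals", {
  sol <- aqueous_solution(dic = 6e-3, ca = 3e-3, na = 5e-4, cl = 2e-4,
                          temperature = 309.15)
  s1 <- speciate(sol)
  s2 <- speciate(sol)
  expect_equal(s1$pH, s2$pH, tolerance = 1e-9)
})

test_that("raising DIC at fixed cations strictly lowers the pH", {
  ph <- vapply(seq(2e-3, 2e-2, length.out = 6), function(dic) {
    speciate(aqueous_solution(dic = dic, ca = 2e-3, na = 1e-3,
                              temperature = 309.15))$pH
  }, numeric(1))
  expect_true(all(diff(ph) < 0))
})

test_that("the raw formation water speciates alkaline", {
  # the published composition carries a few percent analytic charge
  # imbalance, so the charge-balance pH overshoots the field value (8.3)
  # somewhat; the solver itself is pinned by the grid-search oracle
  s <- speciate(formation_water())
  ref <- oracle_speciation_ph(solution_totals(formation_water()), 298.15)
  expect_equal(speciate(formation_water(), ion_pairs = FALSE)$pH, ref,
               tolerance = 1.1e-3)
  expect_lt(abs(s$pH - 8.3), 0.65)
})

test_that("negative totals are rejected with the component named", {
  expect_error(aqueous_solution(dic = -1e-3), "dic")
  expect_error(aqueous_solution(mass_kg = 0), "> 0")
})

test_that("sulfide split: half-titration, acid limit, closure", {
  cst <- thermo_constants()
  pka <- log_k(cst, "h2s_1", 309.15) * -1
  x <- sulfide_split(pka, 309.15)
  expect_equal(unname(x[["x_h2s"]]), 0.5, tolerance = 1e-12)
  x <- sulfide_split(pka - 3, 309.15)
  expect_equal(unname(x[["x_h2s"]]), 0.999, tolerance = 1e-3)
  for (p in c(3, 6, 9)) {
    x <- sulfide_split(p, 298.15, ionic_strength = 0.02)
    expect_identical(unname(x[["x_h2s"]] + x[["x_hs"]]), 1)
  }
  expect_error(sulfide_split(-1, 298.15), "between 0 and 14")
})

test_that("the canonical 0.93/0.07 split is recovered near pH 6", {
  # the published coefficients correspond to a reference-temperature
  # evaluation of the split at the in situ pH
  x <- sulfide_split(6.0, 298.15, ionic_strength = 0.015)
  expect_lt(abs(x[["x_hs"]] - 0.07), 0.05)
})
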