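test_that("every scheme balances H, C, O, S and charge exactly", {
  el <- list(
    "SO4--" = c(0, 0, 4, 1, -2), "H2(aq)" = c(2, 0, 0, 0, 0),
    "CO2(aq)" = c(0, 1, 2, 0, 0), "H2S(aq)" = c(2, 0, 0, 1, 0),
    "HS-" = c(1, 0, 0, 1, -1), "HCO3-" = c(1, 1, 3, 0, -1),
    "H2O(l)" = c(2, 0, 1, 0, 0), "CH3COO-" = c(3, 2, 2, 0, -1),
    "HCOO-" = c(1, 1, 2, 0, -1), "CH4(aq)" = c(4, 1, 0, 0, 0))
  for (nm in c("sulfate_reduction", "acetogenesis",
               "formate_production", "methanogenesis")) {
    for (ph in c(4, 6.05, 8)) {
      sc <- reaction_scheme(nm, pH = ph, temperature = 309.15)
      bal <- Reduce(`+`, purrr::map(names(sc$nu),
                                    ~ sc$nu[[.x]] * el[[.x]]))
      expect_lt(max(abs(bal)), 1e-10)
    }
  }
})

test_that("the frozen 0.93/0.07 split reproduces the canonical scheme", {
  sc <- reaction_scheme("sulfate_reduction",
                        split = c(x_h2s = 0.93, x_hs = 0.07))
  expect_equal(sc$nu[["H2S(aq)"]], 0.93)
  expect_equal(sc$nu[["HS-"]], 0.07)
  expect_equal(sc$nu[["CO2(aq)"]], -1.93)
  expect_equal(sc$nu[["HCO3-"]], 1.93)
  expect_equal(sc$nu[["H2O(l)"]], 2.07)
  expect_equal(sc$h2_per_extent, 4)
  expect_equal(sc$ic_per_extent, 0)   # CO2 consumed returns as HCO3-
})

test_that("H2 and inorganic-carbon demands per extent are as expected", {
  expect_equal(reaction_scheme("acetogenesis")$h2_per_extent, 4)
  expect_equal(reaction_scheme("acetogenesis")$ic_per_extent, 2)
  expect_equal(reaction_scheme("formate_production")$h2_per_extent, 1)
  expect_equal(reaction_scheme("formate_production")$ic_per_extent, 1)
  expect_equal(reaction_scheme("methanogenesis")$h2_per_extent, 4)
  expect_equal(reaction_scheme("methanogenesis")$ic_per_extent, 1)
  # methanogenesis is pH-independent
  expect_identical(reaction_scheme("methanogenesis", pH = 4)$nu,
                   reaction_scheme("methanogenesis", pH = 10)$nu)
  expect_error(reaction_scheme("fermentation"), "valid schemes")
})

test_that("the mass ledger tracks the study's water history", {
  expect_equal(ledger_mass(mass_ledger(event_timeline(), 1.85), 50), 1.85)
  tl <- event_timeline(events = data.frame(
    day = c(0.1, 17, 17), kind = c("liquid_withdrawal", "water_addition",
                                   "water_addition"),
    species = c("mass", "mass", "so4"), value = c(0.100, 0.353, 7.0e-4)))
  led <- mass_ledger(tl, 1.950)
  expect_equal(ledger_mass(led, 18), 1.950 - 0.100 + 0.353)
  expect_equal(led$additions$mol, 0.353 * 7.0e-4)
  # withdrawing everything is an error naming the event
  bad <- event_timeline(events = data.frame(
    day = 5, kind = "liquid_withdrawal", species = "mass", value = 2))
  expect_error(mass_ledger(bad, 1.85), "day 5")
})

test_that("sampling convention: same-day withdrawal follows measurement", {
  tl <- event_timeline(events = data.frame(
    day = c(10, 20), kind = "liquid_withdrawal", species = "mass",
    value = 0.05))
  led <- mass_ledger(tl, 1)
  expect_equal(ledger_mass(led, 10), 1)       # measured before sampling
  expect_equal(ledger_mass(led, 15), 0.95)
  expect_equal(ledger_mass(led, 20), 0.95)
  expect_equal(ledger_mass(led, 21), 0.90)
})
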