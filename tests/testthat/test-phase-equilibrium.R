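test_that("Henry dissolution evaluates the pinned correlations", {
  expect_identical(dissolve_gas("CO2", 0, 309.15), 0)
  # values frozen from evaluating the constants-file correlations
  expect_equal(dissolve_gas("CO2", 0.31, 309.15), 7.888392e-3,
               tolerance = 1e-6)
  expect_equal(dissolve_gas("H2", 1.2, 309.15), 8.870908e-4,
               tolerance = 1e-6)
  expect_error(dissolve_gas("Xe", 1, 309.15), "constants file")
})

test_that("an acid-base inert headspace leaves the pH unchanged", {
  w <- aqueous_solution(temperature = 309.15)
  ref <- speciate(w)$pH
  st <- reactor_state(gas_phase(CH4 = 1, temperature = 309.15,
                                pressure = 40), w)
  eq <- equilibrate(st, calcite = FALSE)
  expect_equal(eq$speciation$pH, ref, tolerance = 0.01)
})

test_that("equilibration conserves elements and is idempotent", {
  st <- reactor_state(
    gas_phase(CH4 = 4.54, CO2 = 4.58e-2, H2 = 0.106,
              temperature = 309.15, pressure = 62),
    mixed_water(1.85, temperature = 309.15), calcite_mol = 0.5)
  eq <- equilibrate(st)
  expect_lt(eq$diagnostics$conservation, 1e-10)
  eq2 <- equilibrate(eq)
  expect_equal(eq2$speciation$pH, eq$speciation$pH, tolerance = 1e-8)
  expect_equal(eq2$gas$amounts[["CO2"]], eq$gas$amounts[["CO2"]],
               tolerance = 1e-8)
})

test_that("fugacity equals the Henry-law activity for every volatile", {
  st <- reactor_state(
    gas_phase(CH4 = 2, CO2 = 0.03, H2 = 0.05, temperature = 309.15,
              pressure = 40),
    mixed_water(1, temperature = 309.15))
  eq <- equilibrate(st, calcite = FALSE)
  tot <- solution_totals(eq$solution)
  for (sp in c("CH4", "H2")) {
    expect_equal(tot[[tolower(sp)]] / dissolve_gas(sp, 1, 309.15),
                 unname(eq$gas$fugacities[[sp]]), tolerance = 1e-7)
  }
  co2_aq <- eq$speciation$species$molality[
    eq$speciation$species$species == "CO2(aq)"]
  expect_equal(co2_aq / dissolve_gas("CO2", 1, 309.15),
               unname(eq$gas$fugacities[["CO2"]]), tolerance = 1e-7)
})

test_that("raising the CO2 load never raises the equilibrium pH", {
  ph <- vapply(c(0.01, 0.03, 0.09, 0.27), function(n) {
    st <- reactor_state(
      gas_phase(CH4 = 2, CO2 = n, temperature = 309.15, pressure = 40),
      mixed_water(1, temperature = 309.15))
    equilibrate(st, calcite = FALSE)$speciation$pH
  }, numeric(1))
  expect_true(all(diff(ph) < 0))
})

test_that("calcite dissolution releases Ca and carbonate 1:2", {
  run <- function(n_co2) {
    st <- reactor_state(
      gas_phase(CH4 = 2, CO2 = n_co2, temperature = 309.15,
                pressure = 40),
      mixed_water(1, temperature = 309.15), calcite_mol = 0.5)
    equilibrate(st)
  }
  lo <- run(0.02); hi <- run(0.08)
  d_ca <- solution_totals(hi$solution)[["ca"]] -
    solution_totals(lo$solution)[["ca"]]
  hco3 <- function(s) {
    s$speciation$species$molality[s$speciation$species$species == "HCO3-"]
  }
  expect_gt(d_ca, 0)  # more CO2 dissolves more calcite
  expect_equal((hco3(hi) - hco3(lo)) / d_ca, 2, tolerance = 0.25)
  # saturation index is closed at equilibrium
  expect_lt(abs(hi$speciation$si_calcite), 1e-8)
})

test_that("fixed-pressure mode shrinks the headspace as gas dissolves", {
  st <- reactor_state(
    gas_phase(CH4 = 0.5, CO2 = 0.2, temperature = 309.15, pressure = 30),
    mixed_water(1, temperature = 309.15))
  eq <- equilibrate(st, mode = "fixed_pressure", calcite = FALSE)
  expect_equal(eq$gas$pressure, 30, tolerance = 1e-9)
  expect_lt(eq$gas$volume, st$volume)
  expect_lt(eq$diagnostics$conservation, 1e-10)
})

test_that("a subsaturated inventory at fixed pressure goes single-phase", {
  st <- reactor_state(
    gas_phase(CH4 = 1e-4, CO2 = 5e-5, temperature = 309.15,
              pressure = 60),
    aqueous_solution(mass_kg = 0.5, temperature = 309.15, dic = 1e-3,
                     ca = 5e-4))
  eq <- equilibrate(st, mode = "fixed_pressure", calcite = FALSE)
  expect_true(isTRUE(eq$diagnostics$single_phase))
  expect_equal(sum(eq$gas$amounts), 0)
  # all carbon ends up in solution
  expect_equal(solution_totals(eq$solution)[["dic"]] * 0.5,
               1e-3 * 0.5 + 5e-5, tolerance = 1e-12)
})
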