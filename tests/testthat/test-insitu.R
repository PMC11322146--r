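test_that("null degassing reduces to direct speciation", {
  liq <- c(dic = 5e-3, ca = 2.4e-3, na = 5e-4, cl = 3e-4)
  s <- sample_analysis(liquid = liq, gas_volume_ml = 0,
                       gas_fractions = NULL,
                       sample_temperature = 298.15,
                       reactor_temperature = 298.15,
                       reactor_pressure = 1.01325)
  r <- reconstruct_insitu(s)
  direct <- speciate(aqueous_solution(
    mass_kg = 0.01, temperature = 298.15, dic = 5e-3, ca = 2.4e-3,
    na = 5e-4, cl = 3e-4))
  expect_equal(r$pH_insitu, direct$pH, tolerance = 1e-6)
  expect_equal(r$pH_insitu, r$pH_atmospheric, tolerance = 1e-6)
})

test_that("missing released-gas data degrades gracefully with a warning", {
  s <- sample_analysis(liquid = c(dic = 5e-3, ca = 2.4e-3),
                       gas_volume_ml = NA, gas_fractions = NULL)
  expect_warning(r <- reconstruct_insitu(s), "degraded")
  expect_true(is.finite(r$pH_insitu))
  expect_true(r$degraded)
})

test_that("depressurize/reconstruct closes the round trip", {
  withr::with_seed(7, {
    for (i in 1:8) {
      sol <- aqueous_solution(
        mass_kg = 0.01, temperature = 309.15,
        dic = runif(1, 6e-3, 1.5e-2), ca = runif(1, 1e-3, 5e-3),
        na = runif(1, 0, 2e-3), cl = runif(1, 0, 1e-3),
        acetate = runif(1, 0, 1.5e-3),
        h2 = runif(1, 3e-4, 1.2e-3), ch4 = runif(1, 0.03, 0.06))
      truth <- speciate(sol)
      smp <- depressurize_sample(sol, reactor_temperature = 309.15,
                                 reactor_pressure = 60)
      rec <- reconstruct_insitu(smp)
      expect_equal(rec$pH_insitu, truth$pH, tolerance = 0.02)
    }
  })
})

test_that("gas solubilization acidifies: in situ pH below atmospheric", {
  smp <- ugs_day28_sample()
  r <- reconstruct_insitu(smp)
  expect_lt(r$pH_insitu, r$pH_atmospheric)
})

test_that("redox couples are distinct and reducing on the study sample", {
  r <- reconstruct_insitu(ugs_day28_sample())
  expect_lt(r$e_h2, 0)
  expect_lt(r$e_co2_ch4, 0)
  expect_gt(abs(r$e_h2 - r$e_co2_ch4), 0.02)
})

test_that("Nernst potentials evaluate the printed expressions", {
  # log K = 0, unit activities, pH 0 is the standard hydrogen electrode
  expect_equal(nernst_potential("H+/H2", a_h2 = 1, pH = 0,
                                temperature = 298.15, logk = 0), 0)
  expect_equal(nernst_potential("CO2/CH4", a_co2 = 1, a_ch4 = 1,
                                a_h2o = 1, pH = 0, temperature = 298.15,
                                logk = 0), 0)
  # direct hand evaluation of the two-electron expression
  cst <- thermo_constants()
  lk <- log_k(cst, "h_h2", 309.15)
  hand <- (lk + log10(1 / 9e-4) - 2 * 6.05) *
    log(10) * 8.314 * 309.15 / (2 * 96485)
  expect_equal(nernst_potential("H+/H2", a_h2 = 9e-4, pH = 6.05,
                                temperature = 309.15), hand,
               tolerance = 1e-12)
  expect_error(nernst_potential("H+/H2", a_h2 = 0, pH = 6,
                                temperature = 309.15), "> 0")
})

test_that("Monte-Carlo propagation is reproducible and well-behaved", {
  smp <- ugs_day28_sample()
  # zero uncertainties give zero spread
  smp0 <- smp
  smp0$rel_unc <- list(gas_volume = 0, gas_fractions = 0, liquid = 0,
                       temperature = 0)
  r0 <- propagate_uncertainty(smp0, n_draws = 5, seed = 1)
  expect_lt(max(r0$uncertainty$sd), 1e-12)
  # same seed, same result; different seed, different draws
  r1 <- propagate_uncertainty(smp, n_draws = 40, seed = 11)
  r2 <- propagate_uncertainty(smp, n_draws = 40, seed = 11)
  r3 <- propagate_uncertainty(smp, n_draws = 40, seed = 12)
  expect_identical(r1$uncertainty$sd, r2$uncertainty$sd)
  expect_false(identical(r1$uncertainty$sd, r3$uncertainty$sd))
  expect_error(propagate_uncertainty(smp, n_draws = 1), "at least 2")
})

test_that("default uncertainties give a pH spread of order 0.05-0.1", {
  r <- propagate_uncertainty(ugs_day28_sample(), n_draws = 150, seed = 5)
  sd_ph <- r$uncertainty$sd[r$uncertainty$quantity == "pH_insitu"]
  expect_gt(sd_ph, 0.02)
  expect_lt(sd_ph, 0.2)
})
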