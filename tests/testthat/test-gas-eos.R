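test_that("ideal-gas limit is recovered at vanishing pressure", {
  vm <- pr_molar_volume(c(CH4 = 1), 309.15, 0.001)
  expect_equal(vm, 0.0831446 * 309.15 / 0.001, tolerance = 1e-4)
  phi <- pr_fugacity_coefficients(c(CH4 = 0.8, CO2 = 0.1, H2 = 0.1),
                                  309.15, 1e-3)
  expect_true(all(abs(phi - 1) < 1e-4))
})

test_that("molar volumes match the independent Cardano-cubic oracle", {
  cases <- list(
    list(y = c(CO2 = 1), t = 298.15, p = 1),
    list(y = c(CH4 = 0.978, H2 = 0.022), t = 309.15, p = 60),
    list(y = c(CH4 = 0.973, CO2 = 0.005, H2 = 0.022), t = 309.15, p = 62)
  )
  for (cs in cases) {
    expect_equal(pr_molar_volume(cs$y, cs$t, cs$p),
                 oracle_pr(cs$y, cs$t, cs$p)$Vm, tolerance = 1e-10)
  }
  # frozen oracle values
  expect_equal(pr_molar_volume(c(CO2 = 1), 298.15, 1), 24.65375,
               tolerance = 1e-6)
  expect_equal(pr_molar_volume(c(CH4 = 0.978, H2 = 0.022), 309.15, 60),
               0.3865022, tolerance = 1e-6)
})

test_that("fugacity coefficients match the oracle, incl. near-critical CO2", {
  phi <- pr_fugacity_coefficients(c(CO2 = 1), 309.15, 60)
  expect_equal(unname(phi[["CO2"]]), 0.7256813, tolerance = 1e-6)
  expect_equal(phi, oracle_pr(c(CO2 = 1), 309.15, 60)$phi,
               tolerance = 1e-10)
  # H2 is slightly super-ideal at reactor conditions
  phi_h2 <- pr_fugacity_coefficients(c(H2 = 1), 309.15, 60)
  expect_gt(phi_h2[["H2"]], 1)
  expect_equal(unname(phi_h2[["H2"]]), 1.018346, tolerance = 1e-6)
  y <- c(CH4 = 0.973, CO2 = 0.005, H2 = 0.022)
  expect_equal(pr_fugacity_coefficients(y, 309.15, 60),
               oracle_pr(y, 309.15, 60)$phi, tolerance = 1e-10)
})

test_that("pure-gas ln phi equals the mixture expression at y = 1", {
  for (sp in c("CH4", "CO2", "H2")) {
    pure <- pr_fugacity_coefficients(stats::setNames(1, sp), 309.15, 60)
    mix <- pr_fugacity_coefficients(
      stats::setNames(c(1, 0), c(sp, if (sp == "CO2") "CH4" else "CO2")),
      309.15, 60)
    expect_equal(log(pure[[sp]]), log(mix[[sp]]), tolerance = 1e-10)
  }
})

test_that("vapor-root selection is stable under tiny perturbations", {
  base <- pr_molar_volume(c(CO2 = 1), 309.15, 60)
  for (eps in c(1e-9, -1e-9)) {
    expect_equal(pr_molar_volume(c(CO2 = 1), 309.15 + eps, 60 + eps),
                 base, tolerance = 1e-6)
  }
})

test_that("ideal fallback is adequate for H2 but not for dense CH4", {
  st_pr <- gas_phase(H2 = 1, temperature = 309.15, pressure = 60)
  st_id <- gas_phase(H2 = 1, temperature = 309.15, pressure = 60,
                     ideal = TRUE)
  expect_equal(st_id$volume, st_pr$volume, tolerance = 0.02)
  # CH4 at 60 bar is ~10% non-ideal: the PR correction matters
  expect_lt(pr_molar_volume(c(CH4 = 1), 309.15, 60) /
              (0.0831446 * 309.15 / 60), 0.95)
})

test_that("composition validation rejects bad input", {
  expect_error(pr_molar_volume(c(0.5, 0.5), 309.15, 60), "named")
  expect_error(pr_molar_volume(c(CH4 = 0.7, CO2 = 0.2), 309.15, 60),
               "sum to 1")
  expect_error(pr_fugacity_coefficients(c(XX = 1), 309.15, 60),
               "no Peng-Robinson parameters")
})
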