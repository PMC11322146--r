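test_that("reaction Gibbs energies sum the pinned formation data", {
  # null reaction and reversal antisymmetry
  expect_equal(delta_g_reaction(c("H2O(l)" = -1, "H2O(l)" = 1)), 0)
  nu <- formate_scheme_nu()
  rev <- -nu
  expect_equal(delta_g_reaction(nu), -delta_g_reaction(rev),
               tolerance = 1e-12)
  # hand sum over the pinned NBS entries
  hand <- (-351.0) + (-237.129) - (-586.77) - 17.6
  expect_equal(delta_g_reaction(nu), hand, tolerance = 1e-9)
  expect_equal(hand, -18.959, tolerance = 1e-6)
  expect_error(delta_g_reaction(c("XeO4" = 1)), "XeO4")
})

test_that("Gibbs-Helmholtz limiting cases and the study correction", {
  expect_equal(gibbs_helmholtz(-18.959, -15.24, 298.15), -18.959)
  expect_equal(gibbs_helmholtz(-10, 0, 320, 298.15), -10 * 320 / 298.15)
  # direct evaluation of the integrated form at 36 degC
  direct <- 309.15 * (-18.959 / 298.15 - 15.24 * (1 / 309.15 - 1 / 298.15))
  expect_equal(gibbs_helmholtz(-18.959, -15.24, 309.15), direct,
               tolerance = 1e-12)
  expect_equal(direct, -19.09621, tolerance = 1e-5)
})

test_that("the formate reaction is exothermic: K falls with temperature", {
  k298 <- reaction_thermo(formate_scheme_nu(), 298.15)$K
  k309 <- reaction_thermo(formate_scheme_nu(), 309.15)$K
  expect_lt(reaction_thermo(formate_scheme_nu(), 309.15)$dh, 0)
  expect_lt(k309, k298)
  expect_equal(k309, 1685.2, tolerance = 1e-3)
})

test_that("equilibrium formate is first-order in the H2 activity", {
  m1 <- formate_equilibrium(1e-3, a_hco3 = 5e-3,
                            temperature = 309.15)$formate_molality
  m2 <- formate_equilibrium(2e-3, a_hco3 = 5e-3,
                            temperature = 309.15)$formate_molality
  expect_equal(m2 / m1, 2, tolerance = 1e-12)
  expect_equal(formate_equilibrium(0, a_hco3 = 5e-3,
                                   temperature = 309.15)$formate_molality,
               0)
  expect_error(formate_equilibrium(1e-3, a_hco3 = 0,
                                   temperature = 309.15), "> 0")
})

test_that("the computed equilibrium closes the mass-action quotient", {
  th <- reaction_thermo(formate_scheme_nu(), 309.15)
  fe <- formate_equilibrium(9.7e-4, a_hco3 = 4.3e-3,
                            temperature = 309.15, a_h2o = 0.999)
  q <- fe$formate_activity * 0.999 / (9.7e-4 * 4.3e-3)
  expect_equal(q, th$K, tolerance = 1e-10)
})

test_that("both dissolved-H2 activity paths are exposed and ordered", {
  pp <- dissolved_h2_activity(0.022, 60, 309.15)
  fu <- dissolved_h2_activity(0.022, 60, 309.15, method = "fugacity")
  expect_equal(pp, dissolve_gas("H2", 0.022 * 60, 309.15),
               tolerance = 1e-12)
  expect_gt(fu, pp)    # H2 is super-ideal, phi > 1
  expect_lt(fu / pp, 1.2)
})
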