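test_that("Davies coefficients hit the limiting cases", {
  # neutral species and infinite dilution are exactly 1
  expect_identical(activity_coefficient(0, 0.1, 309.15), 1)
  for (z in -2:2) expect_identical(activity_coefficient(z, 0, 298.15), 1)
})

test_that("Davies formula matches a hand evaluation", {
  # log10(gamma) = -A (sqrt(I)/(1+sqrt(I)) - 0.3 I), A(25C) = 0.5092
  A <- 0.4913 + 6.106e-4 * 25 + 3.65e-6 * 625
  by_hand <- 10^(-A * (sqrt(0.01) / 1.1 - 0.3 * 0.01))
  expect_equal(activity_coefficient(-1, 0.01, 298.15), by_hand,
               tolerance = 1e-12)
  expect_equal(by_hand, 0.902, tolerance = 1e-3)
  # charge enters squared
  expect_equal(activity_coefficient(2, 0.05, 298.15),
               activity_coefficient(-1, 0.05, 298.15)^4,
               tolerance = 1e-12)
})

test_that("gamma tends to 1 uniformly as ionic strength vanishes", {
  Is <- 10^seq(-1, -8, by = -1)
  g <- vapply(Is, function(I) activity_coefficient(-2, I, 309.15),
              numeric(1))
  expect_true(all(diff(abs(g - 1)) < 0)) # monotone approach
  expect_lt(abs(g[length(g)] - 1), 1e-3)
})

test_that("ionic strengths beyond the validity domain are refused", {
  expect_error(activity_coefficient(-1, 0.6, 298.15), "validity domain")
  expect_error(activity_coefficient(1, -0.1, 298.15), ">= 0")
})
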