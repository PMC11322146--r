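test_that("zero rates and zero noise give series constant between events", {
  sc <- synthetic_scenario(
    n_days = 12, rel_noise = 0,
    rates = list(sulfate_reduction = 0, acetogenesis = 0,
                 formate_production = 0, methanogenesis = 0))
  sim <- simulate_reactor(sc)
  so4 <- dplyr::filter(sim$series, species == "so4")
  expect_lt(diff(range(so4$value)), 1e-12)
  # CO2 only moves at the day-7.5 gas top-up and day-9 injection window
  co2 <- dplyr::filter(sim$series, species == "CO2", phase == "gas")
  pre <- co2$value[co2$day %in% 1:7]
  expect_lt(diff(range(pre)), 1e-9)
})

test_that("a scenario is fully reproducible from its seed", {
  sc <- synthetic_scenario(n_days = 6, rel_noise = 0.05, seed = 99)
  s1 <- simulate_reactor(sc)$series
  s2 <- simulate_reactor(sc)$series
  expect_identical(s1$value, s2$value)
  sc2 <- synthetic_scenario(n_days = 6, rel_noise = 0.05, seed = 100)
  expect_false(identical(simulate_reactor(sc2)$series$value, s1$value))
})

test_that("multiplicative noise is unbiased and seed-stable", {
  base <- tibble::tibble(day = seq_len(10000), species = "so4",
                         phase = "aqueous", value = 2e-4, rel_unc = 0.05)
  noisy <- add_noise(base, 0.05, seed = 4)
  se <- 0.05 * 2e-4 / sqrt(10000)
  expect_lt(abs(mean(noisy$value) - 2e-4), 3 * se)
  expect_identical(add_noise(base, 0.05, seed = 4)$value, noisy$value)
  expect_identical(add_noise(base, 0, seed = 4)$value, base$value)
})

test_that("simulator inventories close: total carbon is conserved", {
  sc <- synthetic_scenario(
    n_days = 10, rel_noise = 0,
    rates = list(sulfate_reduction = 0, acetogenesis = 0,
                 formate_production = 0, methanogenesis = 0),
    withdrawal_days = numeric(0), calcite = FALSE)
  sim <- simulate_reactor(sc)
  s <- sim$series
  mass <- function(d) 1.85
  ic <- vapply(unique(s$day), function(d) {
    g <- s$value[s$day == d & s$species == "CO2" & s$phase == "gas"]
    aq <- s$value[s$day == d & s$species == "dic"]
    g + aq * mass(d)
  }, numeric(1))
  injected <- c(rep(0, 8), rep(2e-3, 3))  # day-7.5 CO2 top-up
  expect_lt(max(abs(ic - injected - ic[1])), 1e-9)
})

test_that("substrate caps truncate rates instead of going negative", {
  sc <- synthetic_scenario(
    n_days = 16, rel_noise = 0,
    rates = list(sulfate_reduction = 5e-4, acetogenesis = 0,
                 formate_production = 0, methanogenesis = 0),
    windows = list(sulfate_reduction = c(2, 16), acetogenesis = c(2, 16),
                   formate_production = c(2, 16),
                   methanogenesis = c(2, 16)))
  sim <- simulate_reactor(sc)
  so4 <- dplyr::filter(sim$series, species == "so4")
  expect_true(all(so4$value >= 0))
  expect_equal(min(so4$value), 0, tolerance = 1e-12)
  expect_gt(nrow(sim$truncations), 0)
})

test_that("the default scenario reproduces the study's qualitative shape", {
  sim <- sim_cache$long_sim
  if (is.null(sim)) {
    sim <- simulate_reactor(synthetic_scenario(n_days = 105,
                                               rel_noise = 0))
    sim_cache$long_sim <- sim
  }
  s <- sim$series
  co2 <- dplyr::filter(s, species == "CO2", phase == "gas")
  expect_lt(co2$value[co2$day == 7] / co2$value[co2$day == 0], 0.8)
  so4 <- dplyr::filter(s, species == "so4")
  expect_equal(so4$value[so4$day == 25], 0, tolerance = 1e-10)
  fo <- dplyr::filter(s, species == "formate")
  expect_true(all(diff(fo$value[fo$day >= 14]) > -1e-12))
  h2 <- dplyr::filter(s, species == "H2", phase == "gas")
  expect_lt(h2$value[h2$day == 105], h2$value[h2$day == 9])
})
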