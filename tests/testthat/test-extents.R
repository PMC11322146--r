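make_flat_series <- function() {
  days <- c(0, 10, 20, 40)
  dplyr::bind_rows(
    tibble::tibble(day = days, species = "so4", phase = "aqueous",
                   value = 5e-4, rel_unc = 0.05),
    tibble::tibble(day = days, species = "acetate", phase = "aqueous",
                   value = 1e-4, rel_unc = 0.05),
    tibble::tibble(day = days, species = "formate", phase = "aqueous",
                   value = 1e-4, rel_unc = 0.05),
    tibble::tibble(day = days, species = "dic", phase = "aqueous",
                   value = 5e-3, rel_unc = 0.05),
    tibble::tibble(day = days, species = "ca", phase = "aqueous",
                   value = 2e-3, rel_unc = 0.05),
    tibble::tibble(day = days, species = "CO2", phase = "gas",
                   value = 3e-2, rel_unc = 0.05),
    tibble::tibble(day = days, species = "CH4", phase = "gas",
                   value = 4.6, rel_unc = 0.05),
    tibble::tibble(day = days, species = "H2", phase = "gas",
                   value = 0.1, rel_unc = 0.05)
  )
}

test_that("a constant series yields zero extents everywhere", {
  led <- mass_ledger(event_timeline(), 1.85)
  schemes <- study_schemes(windows = list(
    sulfate_reduction = c(0, 40), acetogenesis = c(0, 40),
    formate_production = c(0, 40), methanogenesis = c(0, 40)))
  ext <- compute_extents(make_flat_series(), schemes, led,
                         dissolved_co2 = "series")
  expect_true(all(abs(ext$intervals$extent) < 1e-14))
  bud <- h2_co2_budget(ext, make_flat_series())
  expect_true(all(abs(diff(bud$curves$h2_modeled[
    bud$curves$day > 0])) < 1e-14))
})

test_that("series validation catches malformed input", {
  s <- make_flat_series()
  expect_error(measurement_series(rbind(s, s[1, ])), "duplicate")
  bad <- s; bad$species[1] <- "phosphate"
  expect_error(measurement_series(bad), "unknown species")
  expect_error(measurement_series(s[, -5]), "rel_unc")
})

test_that("a measurement gap spanning an addition is refused", {
  s <- make_flat_series()
  s <- s[!(s$species == "so4" & s$day %in% c(10, 20)), ]   # 0 -> 40 gap
  tl <- event_timeline(events = data.frame(
    day = c(17, 17), kind = "water_addition", species = c("mass", "so4"),
    value = c(0.3, 7e-4)))
  led <- mass_ledger(tl, 1.85)
  schemes <- study_schemes(windows = list(
    sulfate_reduction = c(0, 40), acetogenesis = c(0, 40),
    formate_production = c(0, 40), methanogenesis = c(0, 40)))
  expect_error(compute_extents(s, schemes, led, dissolved_co2 = "series"),
               "interpolation policy")
})

test_that("negative raw extents are clipped and logged", {
  s <- make_flat_series()
  # acetate *decreases*: a negative raw acetogenesis extent
  s$value[s$species == "acetate"] <- c(4e-4, 3e-4, 2e-4, 1e-4)
  led <- mass_ledger(event_timeline(), 1.85)
  schemes <- study_schemes(windows = list(
    sulfate_reduction = c(0, 40), acetogenesis = c(0, 40),
    formate_production = c(0, 40), methanogenesis = c(0, 40)))
  ext <- compute_extents(s, schemes, led, dissolved_co2 = "series")
  ac <- dplyr::filter(ext$intervals, scheme == "acetogenesis")
  expect_true(all(ac$extent == 0))
  expect_true(all(ac$clipped < 0))
  expect_gt(ext$total_clipped, 0)
})

test_that("extents are zero outside the active window", {
  s <- make_flat_series()
  s$value[s$species == "so4"] <- c(5e-4, 4e-4, 3e-4, 2e-4)
  led <- mass_ledger(event_timeline(), 1.85)
  schemes <- study_schemes(windows = list(
    sulfate_reduction = c(15, 40), acetogenesis = c(0, 40),
    formate_production = c(0, 40), methanogenesis = c(0, 40)))
  ext <- compute_extents(s, schemes, led, dissolved_co2 = "series")
  sr <- dplyr::filter(ext$intervals, scheme == "sulfate_reduction")
  expect_equal(sr$extent[sr$day == 10], 0)       # closes before window
  expect_gt(sr$extent[sr$day == 20], 0)
})

test_that("attribution additivity holds exactly", {
  sim <- get_short_sim()
  led <- mass_ledger(sim$timeline, 1.85)
  schemes <- study_schemes(windows = sim$scenario$windows)
  ext <- compute_extents(sim$series, schemes, led,
                         dissolved_co2 = "series")
  bud <- h2_co2_budget(ext, sim$series)
  expect_equal(sum(bud$attribution$h2_mol),
               max(bud$curves$h2_consumed), tolerance = 1e-12)
  expect_equal(sum(bud$attribution$fraction), 1, tolerance = 1e-12)
})

test_that("sulfide production and methane production track the extents", {
  sim <- get_short_sim()
  led <- mass_ledger(sim$timeline, 1.85)
  schemes <- study_schemes(windows = sim$scenario$windows)
  ext <- compute_extents(sim$series, schemes, led,
                         dissolved_co2 = "series")
  g <- glance(ext)
  sr <- g[g$scheme == "sulfate_reduction", ]
  expect_equal(sr$sulfide_produced, sr$extent, tolerance = 1e-12)
  expect_equal(sr$h2_consumed, 4 * sr$extent, tolerance = 1e-12)
})
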