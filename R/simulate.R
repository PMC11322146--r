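# Forward reactor simulator: a daily loop of events, zero-order microbial
# reaction steps with hard substrate caps, and full gas-liquid(-calcite)
# re-equilibration.  Ground-truth extents are recorded alongside the
# observables so the inverse pipeline can be validated end to end.

#' Define a synthetic reactor scenario
#'
#' Defaults mirror the studied experiment: a 62 bar CH4/CO2 charge at
#' 36 degC over 1.85 kg of the mixed formation water in contact with
#' calcite-bearing rock; a gas top-up on day 7.5, a 2.2 mol% H2 injection
#' on day 9, a 0.353 kg water addition on day 17, and a 0.02 kg sampling
#' withdrawal on every measurement day.  Microbial reactions run at
#' zero-order rates inside onset windows, capped so no substrate goes
#' negative (sulfate exhaustion ends sulfate reduction, as observed around
#' day 15).
#'
#' @param n_days Simulation span (days).
#' @param rates Named list of zero-order rates (mol extent/day) for
#'   `sulfate_reduction`, `acetogenesis`, `formate_production`,
#'   `methanogenesis`.
#' @param windows Named list of onset windows (days) for the four schemes.
#' @param rel_noise Relative s.d. of the multiplicative measurement noise
#'   (0.05 matches the instruments' 5 % precision).
#' @param seed Random seed; a scenario fully determines its realisation.
#' @param initial_state Optional [reactor_state()] overriding the default
#'   initial charge.
#' @param timeline Optional [event_timeline()] overriding the default
#'   events.
#' @param calcite Calcite pool reacts (default TRUE).
#' @param measurement_days Days on which observables are recorded (and the
#'   routine withdrawal taken).  Default: every day.
#' @param withdrawal_kg Routine sampling withdrawal mass (kg).
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(
    n_days = 105,
    rates = list(sulfate_reduction = 2.2e-4, acetogenesis = 2.5e-5,
                 formate_production = 6.5e-5, methanogenesis = 9e-5),
    windows = list(sulfate_reduction = c(9, 21), acetogenesis = c(9, 105),
                   formate_production = c(14, 105),
                   methanogenesis = c(35, 105)),
    rel_noise = 0.05, seed = 1,
    initial_state = NULL, timeline = NULL, calcite = TRUE,
    measurement_days = NULL, withdrawal_days = NULL,
    withdrawal_kg = 0.02) {
  if (any(unlist(rates) < 0)) stop("rates must be >= 0", call. = FALSE)
  if (rel_noise < 0) stop("rel_noise must be >= 0", call. = FALSE)
  windows <- purrr::map(windows, function(w) {
    if (w[1] < 0) {
      stop("scheme windows cannot start before day 0", call. = FALSE)
    }
    # a window starting beyond the span is simply never active
    c(min(w[1], n_days), min(w[2], n_days))
  })
  if (is.null(initial_state)) {
    initial_state <- reactor_state(
      gas_phase(CH4 = 4.54, CO2 = 4.58e-2, temperature = 309.15,
                pressure = 62),
      mixed_water(1.85, temperature = 309.15),
      calcite_mol = if (calcite) 0.5 else 0
    )
  }
  if (is.null(measurement_days)) measurement_days <- 0:n_days
  if (is.null(withdrawal_days)) {
    wd0 <- c(3, 9, 10, 14, 15, 21,
             if (n_days >= 28) seq(28, n_days, by = 7))
    withdrawal_days <- intersect(sort(unique(wd0)), measurement_days)
    withdrawal_days <- withdrawal_days[withdrawal_days <= n_days &
                                         withdrawal_days > 0]
  }
  if (is.null(timeline)) {
    wd <- withdrawal_days
    timeline <- event_timeline(events = rbind(
      data.frame(day = 7.5, kind = "gas_injection",
                 species = c("CH4", "CO2"), value = c(0.16, 2.0e-3)),
      data.frame(day = 9, kind = "gas_injection", species = "H2",
                 value = 0.106),
      data.frame(day = 17, kind = "water_addition",
                 species = c("mass", "dic", "ca", "na", "mg", "cl", "so4"),
                 value = c(0.353, 2.4e-3, 1.31e-3, 6.0e-4, 4.4e-4,
                           3.0e-4, 7.0e-4)),
      if (length(wd) > 0) {
        data.frame(day = wd, kind = "liquid_withdrawal",
                   species = "mass", value = withdrawal_kg)
      }
    ))
  }
  structure(
    list(n_days = n_days, rates = rates, windows = windows,
         rel_noise = rel_noise, seed = seed,
         initial_state = initial_state, timeline = timeline,
         calcite = calcite, measurement_days = measurement_days),
    class = "synthetic_scenario"
  )
}

#' Run the forward reactor simulation
#'
#' Daily loop: apply the day's additions, advance every active scheme's
#' extent by its rate (capped so no substrate inventory goes negative),
#' re-equilibrate the phases, record the observables, then take the day's
#' sampling withdrawal.  Multiplicative Gaussian noise is applied to the
#' recorded series at the end with the scenario's seed; the noiseless
#' series and the ground-truth extent trajectory are returned alongside.
#'
#' @param scenario A [synthetic_scenario()].
#' @param constants A [thermo_constants()] object.
#' @return A list of class `reactor_simulation`: `series` (noisy
#'   [measurement_series()]), `series_clean`, `truth` (per-day cumulative
#'   true extents per scheme), `timeline`, `final_state`, and
#'   `truncations` (requested-vs-applied extent differences where a
#'   substrate cap bit).
#' @examples
#' \donttest{
#' sim <- simulate_reactor(synthetic_scenario(n_days = 20))
#' dplyr::filter(sim$series, species == "so4")
#' }
#' @export
simulate_reactor <- function(scenario, constants = default_constants()) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  state <- scenario$initial_state
  tl <- scenario$timeline
  TT <- state$temperature

  schemes <- study_schemes(pH = 6.3, temperature = TT,
                           windows = scenario$windows,
                           constants = constants)

  records <- list()
  truth <- list()
  truncations <- list()
  cum <- stats::setNames(rep(0, length(schemes)), names(schemes))

  for (d in 0:scenario$n_days) {
    if (d == 0) {
      # day 0 records the reactor as charged, before any equilibration —
      # the experiment's day-0 analyses predate gas/water/rock contact
      if (0 %in% scenario$measurement_days) {
        records[[length(records) + 1]] <- record_observables(state, 0)
        truth[[length(truth) + 1]] <- tibble::tibble(
          day = 0, scheme = names(cum), cum_extent = unname(cum))
      }
      state <- equilibrate(state, calcite = scenario$calcite,
                           constants = constants)
      next
    }
    # events due today (additions and gas handling before anything else)
    ev <- tl[tl$day > d - 1 & tl$day <= d & tl$kind != "liquid_withdrawal", ]
    if (nrow(ev) > 0) {
      state <- apply_events(state, ev, constants)
      state <- equilibrate(state, calcite = scenario$calcite,
                           constants = constants)
    }
    # microbial reaction step
    stepped <- FALSE
    for (nm in names(schemes)) {
      w <- scenario$windows[[nm]]
      if (d <= w[1] || d > w[2]) next
      rate <- scenario$rates[[nm]]
      if (rate <= 0) next
      xi <- cap_extent(state, schemes[[nm]], rate, constants)
      if (xi < rate) {
        truncations[[length(truncations) + 1]] <- tibble::tibble(
          day = d, scheme = nm, requested = rate, applied = xi)
      }
      if (xi > 0) {
        state <- apply_reaction(state, schemes[[nm]], xi)
        cum[nm] <- cum[nm] + xi
        stepped <- TRUE
      }
    }
    if (stepped) {
      state <- equilibrate(state, calcite = scenario$calcite,
                           constants = constants)
    }
    if (d %in% scenario$measurement_days) {
      records[[length(records) + 1]] <- record_observables(state, d)
      truth[[length(truth) + 1]] <- tibble::tibble(
        day = d, scheme = names(cum), cum_extent = unname(cum))
    }
    # routine sampling withdrawal after the measurement
    wd <- tl[tl$day > d - 1 & tl$day <= d &
               tl$kind == "liquid_withdrawal", ]
    if (nrow(wd) > 0) {
      state <- apply_withdrawal(state, sum(wd$value))
    }
  }

  clean <- measurement_series(dplyr::bind_rows(records))
  attr(clean, "temperature") <- TT
  noisy <- add_noise(clean, scenario$rel_noise, scenario$seed)
  structure(
    list(series = noisy, series_clean = clean,
         truth = dplyr::bind_rows(truth),
         timeline = tl, final_state = state,
         truncations = dplyr::bind_rows(truncations),
         scenario = scenario),
    class = "reactor_simulation"
  )
}

# largest extent <= rate that keeps every consumed inventory non-negative
cap_extent <- function(state, scheme, rate, constants) {
  kg <- attr(state$solution, "mass_kg")
  tot <- solution_totals(state$solution)
  inv <- state_inventory(state)
  avail <- c(
    "SO4--" = tot[["so4"]] * kg,
    "H2(aq)" = inv[["H2"]],
    "CO2(aq)" = inv[["C"]] - state$calcite_mol,
    "HCO3-" = inv[["C"]] - state$calcite_mol
  )
  cap <- rate
  for (sp in names(scheme$nu)) {
    v <- scheme$nu[[sp]]
    if (v < 0 && sp %in% names(avail)) {
      cap <- min(cap, avail[[sp]] / abs(v))
    }
  }
  max(cap, 0)
}

# apply nu * xi to the reactor inventories (totals bookkeeping; the
# subsequent equilibrate redistributes between phases)
apply_reaction <- function(state, scheme, xi) {
  kg <- attr(state$solution, "mass_kg")
  tot <- solution_totals(state$solution)
  nu <- scheme$nu
  d_ic <- -scheme$ic_per_extent * xi                 # net CO2 + HCO3-
  tot[["dic"]] <- tot[["dic"]] + d_ic / kg
  if ("SO4--" %in% names(nu)) {
    tot[["so4"]] <- max(tot[["so4"]] + nu[["SO4--"]] * xi / kg, 0)
  }
  tot[["sulfide"]] <- tot[["sulfide"]] +
    scheme$sulfide_per_extent * xi / kg
  if ("CH3COO-" %in% names(nu)) {
    tot[["acetate"]] <- tot[["acetate"]] + nu[["CH3COO-"]] * xi / kg
  }
  if ("HCOO-" %in% names(nu)) {
    tot[["formate"]] <- tot[["formate"]] + nu[["HCOO-"]] * xi / kg
  }
  # H2 and CH4 totals live partly in the gas phase: debit/credit the
  # dissolved side and let equilibrate repartition
  gas_n <- state$gas$amounts
  d_h2 <- -scheme$h2_per_extent * xi
  gas_n[["H2"]] <- gas_n[["H2"]] + d_h2
  if (gas_n[["H2"]] < 0) {
    tot[["h2"]] <- max(tot[["h2"]] + gas_n[["H2"]] / kg, 0)
    gas_n[["H2"]] <- 0
  }
  if ("CH4(aq)" %in% names(nu)) {
    if (!"CH4" %in% names(gas_n)) gas_n[["CH4"]] <- 0
    gas_n[["CH4"]] <- gas_n[["CH4"]] + nu[["CH4(aq)"]] * xi
  }
  gas <- do.call(gas_phase, c(as.list(gas_n),
                              list(temperature = state$temperature,
                                   volume = state$volume)))
  sol <- do.call(aqueous_solution, c(
    as.list(tot),
    list(mass_kg = kg, temperature = attr(state$solution, "temperature"),
         charge_offset = attr(state$solution, "charge_offset"))
  ))
  out <- reactor_state(gas, sol, state$calcite_mol)
  out$speciation <- state$speciation
  out
}

apply_events <- function(state, events, constants) {
  gas_n <- state$gas$amounts
  sol <- state$solution
  vol <- state$volume
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    if (e$kind == "gas_injection") {
      if (!e$species %in% names(gas_n)) gas_n[[e$species]] <- 0
      gas_n[[e$species]] <- gas_n[[e$species]] + e$value
    } else if (e$kind == "gas_withdrawal") {
      gas_n[[e$species]] <- max(gas_n[[e$species]] - e$value, 0)
    } else if (e$kind == "piston_move" && e$species == "volume") {
      vol <- e$value
    } else if (e$kind == "water_addition") {
      kg0 <- attr(sol, "mass_kg")
      tot <- solution_totals(sol)
      if (e$species == "mass") {
        kg1 <- kg0 + e$value
        tot <- tot * kg0 / kg1   # dilution
        sol <- do.call(aqueous_solution, c(
          as.list(tot), list(mass_kg = kg1,
                             temperature = attr(sol, "temperature"),
                             charge_offset = attr(sol, "charge_offset"))))
      } else {
        # solute carried by the water added the same day
        madd <- events$value[events$kind == "water_addition" &
                               events$species == "mass" &
                               events$day == e$day]
        kg1 <- attr(sol, "mass_kg")
        tot <- solution_totals(sol)
        tot[[e$species]] <- tot[[e$species]] + e$value * madd / kg1
        sol <- do.call(aqueous_solution, c(
          as.list(tot), list(mass_kg = kg1,
                             temperature = attr(sol, "temperature"),
                             charge_offset = attr(sol, "charge_offset"))))
      }
    }
  }
  gas <- do.call(gas_phase, c(as.list(gas_n),
                              list(temperature = state$temperature,
                                   volume = vol)))
  out <- reactor_state(gas, sol, state$calcite_mol)
  out$speciation <- state$speciation
  out
}

apply_withdrawal <- function(state, mass_kg) {
  kg0 <- attr(state$solution, "mass_kg")
  if (mass_kg >= kg0) {
    stop("withdrawal of ", mass_kg, " kg would empty the reactor (",
         signif(kg0, 4), " kg present)", call. = FALSE)
  }
  # molalities unchanged; solute leaves with the water
  sol <- do.call(aqueous_solution, c(
    as.list(solution_totals(state$solution)),
    list(mass_kg = kg0 - mass_kg,
         temperature = attr(state$solution, "temperature"),
         charge_offset = attr(state$solution, "charge_offset"))
  ))
  out <- reactor_state(state$gas, sol, state$calcite_mol)
  out$speciation <- state$speciation
  out
}

record_observables <- function(state, day) {
  tot <- solution_totals(state$solution)
  gas_n <- state$gas$amounts
  aq <- c("so4", "acetate", "formate", "dic", "ca", "fe", "ba", "h2",
          "ch4")
  dplyr::bind_rows(
    tibble::tibble(day = day, species = names(gas_n), phase = "gas",
                   value = unname(gas_n), rel_unc = 0.05),
    tibble::tibble(day = day, species = aq, phase = "aqueous",
                   value = unname(tot[aq]), rel_unc = 0.05)
  )
}

#' Apply multiplicative measurement noise to a series
#'
#' `value * (1 + rel_sd * z)`, `z ~ N(0, 1)`, reproducible for a given
#' seed; `rel_sd = 0` is the identity.  The caller's RNG state is
#' preserved.
#'
#' @param series A [measurement_series()].
#' @param rel_sd Relative standard deviation (>= 0).
#' @param seed Integer seed.
#' @return The perturbed series.
#' @export
add_noise <- function(series, rel_sd, seed = 1) {
  stopifnot(rel_sd >= 0)
  series <- measurement_series(series)
  if (rel_sd == 0) return(series)
  out <- with_preserved_seed(seed, {
    dplyr::mutate(series,
                  value = .data$value *
                    (1 + stats::rnorm(dplyr::n(), 0, rel_sd)))
  })
  attr(out, "temperature") <- attr(series, "temperature")
  out
}
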