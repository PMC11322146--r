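# Reconstruction of in situ pH and redox potentials from a depressurized
# syringe sample: (1) build total inventories from the liquid analysis and
# the ideal-gas amounts of released gas, (2) model the syringe gas-liquid
# equilibrium at atmospheric pressure — this fixes the CO2(aq)/HCO3- split
# of the measured DIC and records the analytic charge imbalance of the
# water, (3) recompress the inventories to reactor temperature and pressure
# carrying that imbalance as a constant offset, and speciate.

#' Describe a depressurized liquid sample
#'
#' A 10 mL (or so) liquid sample pulled from the pressurized reactor into a
#' gas-tight syringe degasses on depressurization; the released gas volume
#' is read off the syringe, its composition measured after transfer to an
#' N2-flushed vial, and the liquid analysed at atmospheric pressure.
#'
#' @param liquid Named vector of liquid-phase totals at 1 atm (mol/kg):
#'   any of `dic`, `ca`, `mg`, `na`, `k`, `cl`, `so4`, `acetate`,
#'   `formate`, `sulfide`, `fe`, `ba`.  `dic` is the measured dissolved
#'   inorganic carbon (it includes the CO2 retained in solution at 1 atm).
#' @param gas_volume_ml Released gas volume (mL at atmospheric pressure,
#'   read to about 5 %).
#' @param gas_fractions Named mole fractions of the released gas as
#'   measured in the vial, possibly including the `N2` diluent; N2 is
#'   treated as inert and corrected out.
#' @param liquid_mass_kg Liquid aliquot mass (kg).
#' @param sample_temperature Sample temperature at analysis (K).
#' @param reactor_temperature,reactor_pressure Reactor conditions to
#'   reconstruct (K, bar).
#' @param rel_unc Relative (1-sigma) measurement uncertainties used by
#'   [propagate_uncertainty()]: `gas_volume`, `gas_fractions`, `liquid`
#'   (relative) and `temperature` (absolute, K).
#' @return A `sample_analysis` object.
#' @export
sample_analysis <- function(liquid, gas_volume_ml, gas_fractions,
                            liquid_mass_kg = 0.010,
                            sample_temperature = 293.15,
                            reactor_temperature = 309.15,
                            reactor_pressure = 60,
                            rel_unc = list(gas_volume = 0.05,
                                           gas_fractions = 0.05,
                                           liquid = 0.05,
                                           temperature = 0.2)) {
  if (liquid_mass_kg <= 0) stop("liquid mass must be > 0", call. = FALSE)
  if (!is.na(gas_volume_ml) && gas_volume_ml < 0) {
    stop("released gas volume must be >= 0", call. = FALSE)
  }
  if (!is.na(gas_volume_ml) && gas_volume_ml > 0) {
    if (abs(sum(gas_fractions) - 1) > 1e-6) {
      stop("released-gas mole fractions must sum to 1", call. = FALSE)
    }
  }
  structure(
    list(liquid = liquid, gas_volume_ml = gas_volume_ml,
         gas_fractions = gas_fractions, liquid_mass_kg = liquid_mass_kg,
         sample_temperature = sample_temperature,
         reactor_temperature = reactor_temperature,
         reactor_pressure = reactor_pressure, rel_unc = rel_unc),
    class = "sample_analysis"
  )
}

#' Reconstruct reactor-condition pH and redox potentials from a sample
#'
#' Implements the three-step modeling protocol described in the package
#' vignette: released-gas amounts from the ideal-gas law at atmospheric
#' pressure, syringe gas-liquid equilibrium (which yields the
#' atmospheric-pressure pH as a by-product and anchors the CO2(aq)/HCO3-
#' split of the measured DIC), then recompression of the total inventories
#' to reactor conditions.  The charge imbalance of the analysed water is
#' carried unchanged through the recompression, mirroring how geochemical
#' codes conserve imbalance across reaction steps.  Slow redox couples are
#' never equilibrated: the H+/H2 and CO2/CH4 Nernst potentials are computed
#' independently, so their difference measures the redox disequilibrium.
#'
#' @param sample A [sample_analysis()].
#' @param constants A [thermo_constants()] object.
#' @return An `insitu_reconstruction`: in situ pH, atmospheric-pressure pH,
#'   Nernst potentials (V vs SHE) of the H+/H2 and CO2/CH4 couples,
#'   reconstructed dissolved-gas molalities, the in situ [speciate()]
#'   result, and the carried charge offset.  Uncertainties are attached by
#'   [propagate_uncertainty()].
#' @examples
#' s <- sample_analysis(
#'   liquid = c(dic = 7.1e-3, ca = 4.9e-3, mg = 4.4e-4, na = 6.0e-4,
#'              k = 1.5e-4, cl = 1.97e-3, acetate = 1.4e-3,
#'              formate = 1.9e-3),
#'   gas_volume_ml = 15, gas_fractions = c(CH4 = 0.90, CO2 = 0.07,
#'                                         H2 = 0.02, N2 = 0.01)
#' )
#' r <- reconstruct_insitu(s)
#' r$pH_insitu
#' @export
reconstruct_insitu <- function(sample, constants = default_constants()) {
  stopifnot(inherits(sample, "sample_analysis"))
  Ts <- sample$sample_temperature
  Tr <- sample$reactor_temperature
  Pr <- sample$reactor_pressure
  kg <- sample$liquid_mass_kg
  p_atm <- constants$p_atm

  liquid <- expand_liquid(sample$liquid)
  no_gas_data <- is.na(sample$gas_volume_ml) ||
    (sample$gas_volume_ml > 0 && (is.null(sample$gas_fractions) ||
                                  all(is.na(sample$gas_fractions))))
  if (no_gas_data) {
    warning("released-gas data missing; falling back to liquid-only ",
            "speciation (degraded mode)", call. = FALSE)
    sol <- do.call(aqueous_solution,
                   c(as.list(liquid),
                     list(mass_kg = kg, temperature = Tr)))
    spc <- speciate(sol, constants)
    return(new_insitu(spc, pH_atm = NA_real_, sample = sample,
                      charge_offset = 0, constants = constants,
                      degraded = TRUE))
  }

  if (sample$gas_volume_ml == 0) {
    # null degassing: the liquid analysis is the complete inventory
    sol_s <- do.call(aqueous_solution,
                     c(as.list(liquid),
                       list(mass_kg = kg, temperature = Ts)))
    spc_s <- speciate(sol_s, constants)
    offset <- attr(sol_s, "charge_offset")
    sol_r <- do.call(aqueous_solution,
                     c(as.list(liquid),
                       list(mass_kg = kg, temperature = Tr,
                            charge_offset = offset)))
    spc_r <- speciate(sol_r, constants)
    return(new_insitu(spc_r, pH_atm = spc_s$pH, sample = sample,
                      charge_offset = offset, constants = constants))
  }

  # step 1 — released-gas amounts (ideal gas at 1 atm), N2 corrected out
  y <- sample$gas_fractions
  y <- y[setdiff(names(y), "N2")]
  y <- y / sum(y)
  n_gas <- y * p_atm * (sample$gas_volume_ml / 1000) / (RGAS_LBAR * Ts)

  # step 2 — syringe equilibrium at 1 atm: the measured gas composition
  # imposes the retained CO2(aq), which splits the measured DIC
  f_syr <- y * p_atm     # phi = 1 at atmospheric pressure
  m_co2_ret <- if ("CO2" %in% names(y)) {
    dissolve_gas("CO2", f_syr[["CO2"]], Ts, constants)
  } else 0
  if (m_co2_ret >= liquid[["dic"]]) {
    stop("retained CO2(aq) implied by the released-gas composition (",
         signif(m_co2_ret, 3), " mol/kg) exceeds the measured DIC (",
         signif(liquid[["dic"]], 3), " mol/kg); inconsistent sample",
         call. = FALSE)
  }
  liquid_syr <- liquid
  for (sp in intersect(names(y), c("H2", "CH4"))) {
    liquid_syr[[VOL_COMPONENT[[sp]]]] <- dissolve_gas(sp, f_syr[[sp]], Ts,
                                                      constants)
  }
  fn <- function(p) {
    aq_eval(p, liquid_syr, Ts, constants)$molality[["CO2(aq)"]] - m_co2_ret
  }
  pH_atm <- stats::uniroot(fn, c(2, 12), tol = 1e-12)$root
  ev_syr <- aq_eval(pH_atm, liquid_syr, Ts, constants)
  offset <- ev_syr$imbalance

  # step 3 — recompress total inventories to reactor conditions
  tot_r <- liquid
  tot_r[["dic"]] <- liquid[["dic"]] + gas_amount(n_gas, "CO2") / kg
  tot_r[["h2"]] <- liquid_syr[["h2"]] + gas_amount(n_gas, "H2") / kg
  tot_r[["ch4"]] <- liquid_syr[["ch4"]] + gas_amount(n_gas, "CH4") / kg
  if ("H2S" %in% names(n_gas)) {
    tot_r[["sulfide"]] <- liquid[["sulfide"]] +
      gas_amount(n_gas, "H2S") / kg
  }
  sol_r <- do.call(aqueous_solution,
                   c(as.list(tot_r),
                     list(mass_kg = kg, temperature = Tr,
                          charge_offset = offset)))
  vols <- c(CH4 = tot_r[["ch4"]] * kg, CO2 = tot_r[["dic"]] * kg,
            H2 = tot_r[["h2"]] * kg, S = tot_r[["sulfide"]] * kg)
  vols <- vols[vols > 0]
  bub <- bubble_pressure(vols, kg, solution_totals(sol_r), Tr, offset,
                         constants, ideal_gas = FALSE)
  if (bub <= Pr) {
    spc_r <- speciate(sol_r, constants)
  } else {
    # a residual headspace persists at reactor pressure
    seed <- pmax(vols * 0.05, 1e-10)
    names(seed) <- sub("^S$", "H2S", names(seed))
    gas_r <- do.call(gas_phase, c(as.list(seed),
                                  list(temperature = Tr, pressure = Pr)))
    st <- reactor_state(gas_r, solution_update(
      sol_r,
      dic = tot_r[["dic"]] - gas_amount(seed, "CO2") / kg,
      h2 = tot_r[["h2"]] - gas_amount(seed, "H2") / kg,
      ch4 = tot_r[["ch4"]] - gas_amount(seed, "CH4") / kg
    ))
    eq <- equilibrate(st, mode = "fixed_pressure", calcite = FALSE,
                      constants = constants)
    spc_r <- eq$speciation
  }
  new_insitu(spc_r, pH_atm = pH_atm, sample = sample,
             charge_offset = offset, constants = constants)
}

gas_amount <- function(n, sp) if (sp %in% names(n)) n[[sp]] else 0

# fill a partial liquid-analysis vector with zeros for absent components
expand_liquid <- function(liquid) {
  full <- c(dic = 0, sulfide = 0, na = 0, k = 0, ca = 0, mg = 0, cl = 0,
            so4 = 0, acetate = 0, formate = 0, fe = 0, ba = 0,
            h2 = 0, ch4 = 0)
  unknown <- setdiff(names(liquid), names(full))
  if (length(unknown) > 0) {
    stop("unknown liquid component(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(names(full), collapse = ", "), call. = FALSE)
  }
  full[names(liquid)] <- liquid
  full
}

new_insitu <- function(spc, pH_atm, sample, charge_offset, constants,
                       degraded = FALSE) {
  a_h2 <- species_activity(spc, "H2(aq)")
  a_ch4 <- species_activity(spc, "CH4(aq)")
  a_co2 <- species_activity(spc, "CO2(aq)")
  e_h2 <- if (a_h2 > 0) {
    nernst_potential("H+/H2", spc, constants = constants)
  } else NA_real_
  e_c <- if (a_co2 > 0 && a_ch4 > 0) {
    nernst_potential("CO2/CH4", spc, constants = constants)
  } else NA_real_
  structure(
    list(pH_insitu = spc$pH, pH_atmospheric = pH_atm,
         e_h2 = e_h2, e_co2_ch4 = e_c,
         dissolved = c(h2 = spc$totals[["h2"]], ch4 = spc$totals[["ch4"]],
                       co2 = spc$species$molality[
                         spc$species$species == "CO2(aq)"]),
         speciation = spc, charge_offset = charge_offset,
         sample = sample, degraded = degraded,
         uncertainty = NULL),
    class = "insitu_reconstruction"
  )
}

#' @export
print.insitu_reconstruction <- function(x, ...) {
  cat("<insitu_reconstruction>\n")
  cat("  in situ pH       ", format(x$pH_insitu, digits = 4), "\n")
  cat("  atmospheric pH   ", format(x$pH_atmospheric, digits = 4), "\n")
  cat("  E(H+/H2)         ", format(x$e_h2, digits = 4), "V\n")
  cat("  E(CO2/CH4)       ", format(x$e_co2_ch4, digits = 4), "V\n")
  if (!is.null(x$uncertainty)) {
    cat("  pH uncertainty   +/-", format(x$uncertainty$sd[
      x$uncertainty$quantity == "pH_insitu"], digits = 2), "\n")
  }
  invisible(x)
}

#' Nernst potential of a redox couple
#'
#' Evaluates the theoretical single-couple potentials
#' \deqn{E_{H^+/H_2} = \left(\log K + \log\frac{1}{a_{H_2}} - 2\,pH\right)
#'   \frac{\ln(10) R T}{2F}}
#' \deqn{E_{CO_2/CH_4} = \left(\log K +
#'   \log\frac{a_{CO_2}}{a_{CH_4} a_{H_2O}^2} - 8\,pH\right)
#'   \frac{\ln(10) R T}{8F}}
#' with the half-reaction log K taken from the constants file.  Because no
#' global redox equilibrium is imposed, different couples generally give
#' different potentials; their spread quantifies the redox disequilibrium
#' of the water.
#'
#' @param couple `"H+/H2"` or `"CO2/CH4"`.
#' @param speciation A [speciate()] result supplying pH and activities;
#'   individual activities can be overridden.
#' @param a_h2,a_co2,a_ch4,a_h2o Activity overrides (dimensionless).
#' @param pH pH override.
#' @param temperature Temperature (K); defaults to the speciation's.
#' @param logk Half-reaction log K override (defaults to the constants-file
#'   value at `temperature`); the half-reaction constants are data, not
#'   code, because published databases disagree on them.
#' @param constants A [thermo_constants()] object.
#' @return Potential in V versus the standard hydrogen electrode.
#' @export
nernst_potential <- function(couple = c("H+/H2", "CO2/CH4"),
                             speciation = NULL, a_h2 = NULL, a_co2 = NULL,
                             a_ch4 = NULL, a_h2o = NULL, pH = NULL,
                             temperature = NULL, logk = NULL,
                             constants = default_constants()) {
  couple <- match.arg(couple)
  if (!is.null(speciation)) {
    if (is.null(pH)) pH <- speciation$pH
    if (is.null(temperature)) temperature <- speciation$temperature
    if (is.null(a_h2o)) a_h2o <- speciation$water_activity
    if (is.null(a_h2)) a_h2 <- species_activity(speciation, "H2(aq)")
    if (is.null(a_co2)) a_co2 <- species_activity(speciation, "CO2(aq)")
    if (is.null(a_ch4)) a_ch4 <- species_activity(speciation, "CH4(aq)")
  }
  if (is.null(a_h2o)) a_h2o <- 1
  if (is.null(pH) || is.null(temperature)) {
    stop("pH and temperature are required (directly or via a speciation)",
         call. = FALSE)
  }
  RT <- constants$R * temperature * log(10)
  if (couple == "H+/H2") {
    if (is.null(a_h2) || a_h2 <= 0) {
      stop("a(H2) must be > 0 for the H+/H2 couple", call. = FALSE)
    }
    lk <- if (is.null(logk)) log_k(constants, "h_h2", temperature) else logk
    (lk + log10(1 / a_h2) - 2 * pH) * RT / (2 * constants$F)
  } else {
    if (is.null(a_co2) || is.null(a_ch4) || a_co2 <= 0 || a_ch4 <= 0) {
      stop("a(CO2) and a(CH4) must be > 0 for the CO2/CH4 couple",
           call. = FALSE)
    }
    lk <- if (is.null(logk)) log_k(constants, "co2_ch4", temperature) else logk
    (lk + log10(a_co2 / (a_ch4 * a_h2o^2)) - 8 * pH) * RT /
      (8 * constants$F)
  }
}

#' Monte-Carlo uncertainty propagation for the in situ reconstruction
#'
#' Perturbs every measured input of a [sample_analysis()] with its stated
#' uncertainty (multiplicative Gaussian for relative uncertainties,
#' additive for temperatures), reruns [reconstruct_insitu()] for each draw,
#' and reports the standard deviations of the in situ pH and the two Nernst
#' potentials.  The random-number state is derived from `seed` and restored
#' afterwards, so results are reproducible and the session RNG is
#' untouched.
#'
#' @param sample A [sample_analysis()].
#' @param n_draws Number of Monte-Carlo draws (>= 2; 2000 reproduces the
#'   study protocol, a few hundred is enough for 2-digit uncertainties).
#' @param seed Integer seed.
#' @param constants A [thermo_constants()] object.
#' @return The [reconstruct_insitu()] result for the unperturbed sample
#'   with an `uncertainty` tibble attached (quantity, mean, sd over draws).
#' @export
propagate_uncertainty <- function(sample, n_draws = 2000, seed = 1,
                                  constants = default_constants()) {
  stopifnot(inherits(sample, "sample_analysis"))
  if (n_draws < 2) stop("n_draws must be at least 2", call. = FALSE)
  u <- sample$rel_unc
  base <- reconstruct_insitu(sample, constants)

  draws <- with_preserved_seed(seed, {
    purrr::map(seq_len(n_draws), function(i) {
      s <- sample
      s$gas_volume_ml <- s$gas_volume_ml *
        (1 + stats::rnorm(1, 0, u$gas_volume))
      gf <- s$gas_fractions *
        (1 + stats::rnorm(length(s$gas_fractions), 0, u$gas_fractions))
      s$gas_fractions <- pmax(gf, 0) / sum(pmax(gf, 0))
      s$liquid <- pmax(
        s$liquid * (1 + stats::rnorm(length(s$liquid), 0, u$liquid)), 0)
      s$sample_temperature <- s$sample_temperature +
        stats::rnorm(1, 0, u$temperature)
      s$reactor_temperature <- s$reactor_temperature +
        stats::rnorm(1, 0, u$temperature)
      r <- tryCatch(suppressWarnings(reconstruct_insitu(s, constants)),
                    error = function(e) NULL)
      if (is.null(r)) return(NULL)
      c(pH_insitu = r$pH_insitu, e_h2 = r$e_h2, e_co2_ch4 = r$e_co2_ch4)
    })
  })
  mat <- do.call(rbind, purrr::compact(draws))
  base$uncertainty <- tibble::tibble(
    quantity = colnames(mat),
    mean = colMeans(mat),
    sd = apply(mat, 2, stats::sd),
    n_draws = nrow(mat)
  )
  base
}

# run code with a private RNG stream, restoring the caller's state
with_preserved_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate depressurization of a reactor liquid sample
#'
#' Forward model of the syringe sampling: an aliquot of reactor liquid
#' (with its in situ dissolved-gas totals) is flashed to a lower pressure
#' at the sample temperature; the gas that comes out of solution is
#' reported the way the laboratory reads it (volume at the flash pressure,
#' composition of the released gas), together with the residual liquid
#' analysis.  Feeding the result into [reconstruct_insitu()] closes the
#' round trip.
#'
#' @param solution An [aqueous_solution()] holding the in situ totals
#'   (dic including the dissolved CO2, dissolved `h2`, `ch4`, `sulfide`)
#'   at the sample temperature.
#' @param pressure Flash pressure (bar); default atmospheric.
#' @param reactor_temperature,reactor_pressure Conditions recorded in the
#'   returned [sample_analysis()].
#' @param constants A [thermo_constants()] object.
#' @return A [sample_analysis()] describing the flashed sample.
#' @export
depressurize_sample <- function(solution, pressure = NULL,
                                reactor_temperature = 309.15,
                                reactor_pressure = 60,
                                constants = default_constants()) {
  stopifnot(inherits(solution, "aqueous_solution"))
  if (is.null(pressure)) pressure <- constants$p_atm
  Ts <- attr(solution, "temperature")
  kg <- attr(solution, "mass_kg")
  tot <- solution_totals(solution)

  # seed the flash with part of each volatile inventory in the gas phase
  seed <- c(CH4 = tot[["ch4"]], CO2 = 0.3 * tot[["dic"]],
            H2 = tot[["h2"]], H2S = 0.3 * tot[["sulfide"]]) * kg * 0.5
  seed <- seed[seed > 0]
  if (length(seed) == 0) {
    stop("solution holds no volatile inventory to flash", call. = FALSE)
  }
  upd <- list()
  for (sp in names(seed)) {
    cmp <- VOL_COMPONENT[[sp]]
    upd[[cmp]] <- tot[[cmp]] - seed[[sp]] / kg
  }
  sol0 <- do.call(solution_update, c(list(solution), upd))
  gas0 <- do.call(gas_phase, c(as.list(seed),
                               list(temperature = Ts,
                                    pressure = pressure)))
  eq <- equilibrate(reactor_state(gas0, sol0), mode = "fixed_pressure",
                    calcite = FALSE, constants = constants)

  liq <- solution_totals(eq$solution)
  keep <- c("dic", "sulfide", "na", "k", "ca", "mg", "cl", "so4",
            "acetate", "formate", "fe", "ba")
  n_gas <- eq$gas$amounts
  sample_analysis(
    liquid = liq[keep],
    gas_volume_ml = eq$gas$volume * 1000,
    gas_fractions = eq$gas$fractions,
    liquid_mass_kg = kg,
    sample_temperature = Ts,
    reactor_temperature = reactor_temperature,
    reactor_pressure = reactor_pressure
  )
}
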