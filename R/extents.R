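# Extent-of-reaction inversion: turn the measured time series into
# per-interval and cumulative extents of the four metabolisms, correcting
# every interval for the water additions and sampling withdrawals recorded
# in the mass ledger.

GAS_SPECIES <- c("CH4", "CO2", "H2", "H2S")
AQ_SPECIES <- c("so4", "acetate", "formate", "dic", "ca", "mg", "na", "k",
                "cl", "fe", "ba", "h2", "ch4")

#' Validate a measurement series
#'
#' A measurement series is a long tibble with columns `day`, `species`,
#' `phase` (`"gas"` or `"aqueous"`), `value` (mol for gas, mol/kg for
#' aqueous) and `rel_unc` (relative 1-sigma uncertainty).
#'
#' @param series A data frame.
#' @return The validated series (sorted), class `measurement_series`.
#' @export
measurement_series <- function(series) {
  s <- tibble::as_tibble(series)
  need <- c("day", "species", "phase", "value", "rel_unc")
  missing_cols <- setdiff(need, names(s))
  if (length(missing_cols) > 0) {
    stop("measurement series lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_phase <- setdiff(unique(s$phase), c("gas", "aqueous"))
  if (length(bad_phase) > 0) {
    stop("unknown phase(s): ", paste(bad_phase, collapse = ", "),
         call. = FALSE)
  }
  bad_gas <- setdiff(unique(s$species[s$phase == "gas"]), GAS_SPECIES)
  bad_aq <- setdiff(unique(s$species[s$phase == "aqueous"]), AQ_SPECIES)
  if (length(bad_gas) + length(bad_aq) > 0) {
    stop("unknown species: ",
         paste(c(bad_gas, bad_aq), collapse = ", "),
         "; allowed gas: ", paste(GAS_SPECIES, collapse = ", "),
         "; allowed aqueous: ", paste(AQ_SPECIES, collapse = ", "),
         call. = FALSE)
  }
  dup <- dplyr::count(s, .data$day, .data$species, .data$phase)
  if (any(dup$n > 1)) {
    d <- dup[dup$n > 1, ][1, ]
    stop("duplicate measurement for (day ", d$day, ", ", d$species, ", ",
         d$phase, ")", call. = FALSE)
  }
  if (any(!is.finite(s$value))) stop("non-finite measurement values",
                                     call. = FALSE)
  if (any(s$rel_unc < 0)) stop("negative relative uncertainties",
                               call. = FALSE)
  s <- dplyr::arrange(s, .data$day, .data$phase, .data$species)
  structure(s, class = c("measurement_series", class(s)))
}

series_get <- function(series, sp, ph) {
  out <- series[series$species == sp & series$phase == ph,
                c("day", "value", "rel_unc")]
  dplyr::arrange(out, .data$day)
}

# linear interpolation of a measured quantity at arbitrary days
series_interp <- function(tab, days) {
  if (nrow(tab) == 0) return(rep(NA_real_, length(days)))
  if (nrow(tab) == 1) return(rep(tab$value, length(days)))
  stats::approx(tab$day, tab$value, xout = days, rule = 2)$y
}

#' Invert measured time series into extents of reaction
#'
#' For each scheme, the extent over a measurement interval is the
#' event-corrected mole change of its marker species: `dn = n(t2) - n(t1)
#' + withdrawn - added`, with moles evaluated as molality times the ledger
#' water mass at each endpoint, withdrawals removing solute at the
#' (interpolated) prevailing molality, and additions taken from the
#' ledger.  The methanogenesis extent uses the total-inorganic-carbon
#' change (gas CO2 + dissolved carbonate system) corrected for calcite
#' dissolution via the measured calcium change, minus the inorganic carbon
#' consumed by the other three schemes.  Negative raw extents (measurement
#' noise) are clipped to zero and reported in the `clipped` column; an
#' interval is only counted when its closing day lies inside the scheme's
#' active window.
#'
#' @param series A [measurement_series()].
#' @param schemes Named list of [reaction_scheme()]s (see
#'   [study_schemes()]).
#' @param ledger A [mass_ledger()].
#' @param reactor_pressure Total pressure (bar) used to reconstruct
#'   dissolved-gas inventories from the gas series.
#' @param dissolved_co2 `"reconstruct"` (default): the measured aqueous
#'   DIC is an atmospheric-pressure analysis and the in situ CO2(aq) is
#'   added back from the gas series via Henry's law; `"series"`: the DIC
#'   values already contain the in situ CO2(aq) (the forward simulator
#'   records them this way).
#' @param constants A [thermo_constants()] object.
#' @return An `extent_trajectory`: per-interval tibble (`intervals`) and
#'   per-scheme cumulative tibble (`cumulative`) of extents, H2 and
#'   inorganic-carbon consumption, sulfide production and propagated
#'   sigma.  `tidy()` returns the interval table, `glance()` one row per
#'   scheme with totals.
#' @export
compute_extents <- function(series, schemes, ledger,
                            reactor_pressure = 60,
                            dissolved_co2 = c("reconstruct", "series"),
                            constants = default_constants()) {
  dissolved_co2 <- match.arg(dissolved_co2)
  series <- measurement_series(series)

  res <- list()
  for (nm in names(schemes)) {
    sc <- schemes[[nm]]
    if (sc$marker == "ic") next
    tab <- marker_extents(series, sc, ledger)
    tab$ic_other <- tab$extent * sc$ic_per_extent
    res[[nm]] <- tab
  }
  # methanogenesis needs the other schemes' extents interval-by-interval
  is_ic <- purrr::map_chr(schemes, "marker") == "ic"
  if (any(is_ic)) {
    meth <- schemes[[which(is_ic)[1]]]
    res[[meth$name]] <- ic_extents(series, meth, res, ledger,
                                   reactor_pressure, dissolved_co2,
                                   constants)
  }
  intervals <- dplyr::bind_rows(res)
  intervals$ic_other <- NULL
  intervals <- dplyr::mutate(
    intervals,
    h2_consumed = .data$extent *
      purrr::map_dbl(.data$scheme, ~ schemes[[.x]]$h2_per_extent),
    ic_consumed = .data$extent *
      purrr::map_dbl(.data$scheme, ~ schemes[[.x]]$ic_per_extent),
    sulfide_produced = .data$extent *
      purrr::map_dbl(.data$scheme, ~ schemes[[.x]]$sulfide_per_extent)
  )
  cumulative <- dplyr::mutate(
    dplyr::group_by(intervals, .data$scheme),
    cum_extent = cumsum(.data$extent),
    cum_h2 = cumsum(.data$h2_consumed),
    cum_sigma = sqrt(cumsum(.data$sigma^2))
  )
  cumulative <- dplyr::ungroup(cumulative)
  structure(
    list(intervals = intervals, cumulative = cumulative,
         schemes = schemes, ledger = ledger,
         reactor_pressure = reactor_pressure,
         dissolved_co2 = dissolved_co2,
         total_clipped = sum(abs(intervals$clipped))),
    class = "extent_trajectory"
  )
}

# extent intervals for a direct (single-species) marker
marker_extents <- function(series, scheme, ledger) {
  tab <- series_get(series, scheme$marker, "aqueous")
  if (nrow(tab) < 2) {
    stop("marker species '", scheme$marker, "' needs at least two ",
         "measurements", call. = FALSE)
  }
  ev_days <- c(ledger$additions$day,
               ledger$events$day[ledger$events$kind == "water_addition"])
  uncovered <- ev_days[ev_days > min(tab$day) & ev_days < max(tab$day)]
  gap <- vapply(uncovered, function(d) {
    i <- findInterval(d, tab$day)
    tab$day[i + 1] - tab$day[i] > 21
  }, logical(1))
  if (any(gap)) {
    stop("marker '", scheme$marker, "' has a measurement gap spanning an ",
         "event at day ", paste(uncovered[gap], collapse = ", "),
         "; supply an interpolation policy (add measurements)",
         call. = FALSE)
  }
  mass <- ledger_mass(ledger, tab$day)
  n <- tab$value * mass
  purrr::map_dfr(seq_len(nrow(tab) - 1), function(i) {
    t1 <- tab$day[i]; t2 <- tab$day[i + 1]
    wd <- ledger_withdrawals(ledger, t1, t2)
    withdrawn <- if (nrow(wd) == 0) 0 else {
      sum(-wd$dmass * series_interp(tab, wd$day))
    }
    added <- ledger_added(ledger, scheme$marker, t1, t2)
    dn <- n[i + 1] - n[i] + withdrawn - added
    raw <- scheme$marker_sign * dn
    in_win <- t2 > scheme$window[1] & t2 <= scheme$window[2]
    extent <- if (in_win) max(raw, 0) else 0
    tibble::tibble(
      scheme = scheme$name, t1 = t1, t2 = t2, day = t2,
      extent = extent,
      sigma = sqrt((tab$rel_unc[i] * n[i])^2 +
                     (tab$rel_unc[i + 1] * n[i + 1])^2),
      clipped = if (in_win && raw < 0) raw else 0,
      in_window = in_win
    )
  })
}

# total-inorganic-carbon marker (methanogenesis): gas CO2 + dissolved
# carbonate, calcite-corrected through the calcium series
ic_extents <- function(series, scheme, others, ledger, pressure,
                       dissolved_co2, constants) {
  gco2 <- series_get(series, "CO2", "gas")
  dic <- series_get(series, "dic", "aqueous")
  ca <- series_get(series, "ca", "aqueous")
  if (nrow(gco2) < 2 || nrow(dic) < 1) {
    stop("methanogenesis inversion needs gas CO2 and aqueous dic series",
         call. = FALSE)
  }
  days <- gco2$day
  mass <- ledger_mass(ledger, days)
  dic_m <- series_interp(dic, days)
  m_co2_insitu <- if (dissolved_co2 == "reconstruct") {
    co2_aq_from_gas(series, days, pressure, constants)
  } else rep(0, length(days))
  dic_tot <- dic_m + m_co2_insitu
  ic <- gco2$value + dic_tot * mass
  ca_m <- series_interp(ca, days)
  n_ca <- ca_m * mass

  other_iv <- dplyr::bind_rows(others)
  purrr::map_dfr(seq_along(days)[-1], function(i) {
    t1 <- days[i - 1]; t2 <- days[i]
    wd <- ledger_withdrawals(ledger, t1, t2)
    dic_w <- if (nrow(wd) == 0) 0 else {
      sum(-wd$dmass * (series_interp(dic, wd$day) +
                         stats::approx(days, m_co2_insitu, xout = wd$day,
                                       rule = 2)$y))
    }
    ca_w <- if (nrow(wd) == 0) 0 else {
      sum(-wd$dmass * series_interp(ca, wd$day))
    }
    added_ic <- ledger_added(ledger, "dic", t1, t2) +
      event_gas_amount(ledger$timeline, "CO2", t1, t2)
    added_ca <- ledger_added(ledger, "ca", t1, t2)
    d_ic <- ic[i] - ic[i - 1] + dic_w - added_ic
    d_ca <- n_ca[i] - n_ca[i - 1] + ca_w - added_ca
    ic_other <- sum(other_iv$ic_other[other_iv$t2 > t1 &
                                      other_iv$t2 <= t2])
    raw <- (d_ca - d_ic - ic_other) / 1   # ic_per_extent = 1
    in_win <- t2 > scheme$window[1] & t2 <= scheme$window[2]
    extent <- if (in_win) max(raw, 0) else 0
    tibble::tibble(
      scheme = scheme$name, t1 = t1, t2 = t2, day = t2,
      extent = extent,
      sigma = sqrt((gco2$rel_unc[i - 1] * ic[i - 1])^2 +
                     (gco2$rel_unc[i] * ic[i])^2),
      clipped = if (in_win && raw < 0) raw else 0,
      in_window = in_win
    )
  })
}

# in situ CO2(aq) molality reconstructed from the gas series
co2_aq_from_gas <- function(series, days, pressure, constants) {
  g <- list(CH4 = series_get(series, "CH4", "gas"),
            CO2 = series_get(series, "CO2", "gas"),
            H2 = series_get(series, "H2", "gas"))
  amounts <- purrr::map(g, series_interp, days = days)
  amounts <- purrr::map(amounts, ~ ifelse(is.na(.x), 0, .x))
  ntot <- Reduce(`+`, amounts)
  tt <- series_temperature(series)
  vapply(seq_along(days), function(i) {
    y <- vapply(amounts, `[[`, numeric(1), i) / ntot[i]
    y <- y[y > 0]
    phi <- pr_fugacity_coefficients(y, tt, pressure, constants)
    dissolve_gas("CO2", y[["CO2"]] * pressure * phi[["CO2"]], tt,
                 constants)
  }, numeric(1))
}

# temperature attached to a series (constant reactor temperature)
series_temperature <- function(series) {
  tt <- attr(series, "temperature")
  if (is.null(tt)) 309.15 else tt
}

# gas moles of one species injected in (t1, t2]
event_gas_amount <- function(timeline, species, t1, t2) {
  tl <- timeline[timeline$kind == "gas_injection" &
                   timeline$species == species &
                   timeline$day > t1 & timeline$day <= t2, ]
  sum(tl$value) -
    sum(timeline$value[timeline$kind == "gas_withdrawal" &
                         timeline$species == species &
                         timeline$day > t1 & timeline$day <= t2])
}

#' @export
print.extent_trajectory <- function(x, ...) {
  cat("<extent_trajectory>\n")
  print(glance(x))
  if (x$total_clipped > 0) {
    cat("  clipped negative raw extents totalling",
        signif(x$total_clipped, 3), "mol\n")
  }
  invisible(x)
}

#' Modeled H2 and inorganic-carbon budget
#'
#' Integrates the extents into modeled total-H2 and total-CO2 curves:
#' `H2(t) = injected(t) - sum of H2-per-extent x cumulative extent`, with
#' the injected amounts taken from the timeline; the measured totals
#' (headspace amount plus Henry-law dissolved inventory) are attached for
#' comparison, and the per-metabolism attribution of the consumed H2 is
#' tabulated.  Attribution is additive by construction: the per-scheme
#' H2 consumptions sum exactly to the total modeled consumption.
#'
#' @param extents An [compute_extents()] result.
#' @param series The [measurement_series()] the extents came from.
#' @param constants A [thermo_constants()] object.
#' @return An `h2_budget`: `curves` tibble (day, injected, consumed and
#'   modeled H2, measured total H2 and CO2 where available) and an
#'   `attribution` tibble (scheme, H2 mol, fraction of consumption).
#' @export
h2_co2_budget <- function(extents, series, constants = default_constants()) {
  stopifnot(inherits(extents, "extent_trajectory"))
  series <- measurement_series(series)
  tl <- extents$ledger$timeline
  iv <- extents$intervals
  days <- sort(unique(c(0, iv$day, tl$day[tl$kind == "gas_injection"])))

  inj_h2 <- vapply(days, function(d) {
    sum(tl$value[tl$kind == "gas_injection" & tl$species == "H2" &
                   tl$day <= d])
  }, numeric(1))
  cons_h2 <- vapply(days, function(d) sum(iv$h2_consumed[iv$day <= d]),
                    numeric(1))
  cons_ic <- vapply(days, function(d) sum(iv$ic_consumed[iv$day <= d]),
                    numeric(1))

  meas_h2 <- measured_total(series, "H2", extents, constants)
  meas_co2 <- measured_total(series, "CO2", extents, constants)
  curves <- tibble::tibble(
    day = days,
    h2_injected = inj_h2,
    h2_consumed = cons_h2,
    h2_modeled = inj_h2 - cons_h2,
    ic_consumed = cons_ic,
    h2_measured = series_interp_or_na(meas_h2, days),
    co2_measured = series_interp_or_na(meas_co2, days)
  )
  attribution <- dplyr::summarise(
    dplyr::group_by(iv, .data$scheme),
    h2_mol = sum(.data$h2_consumed), .groups = "drop")
  attribution$fraction <- attribution$h2_mol /
    ifelse(sum(attribution$h2_mol) > 0, sum(attribution$h2_mol), 1)
  structure(list(curves = curves, attribution = attribution,
                 measured_h2 = meas_h2, measured_co2 = meas_co2),
            class = "h2_budget")
}

# headspace + Henry-law dissolved total of a volatile at its measured days
measured_total <- function(series, sp, extents, constants) {
  g <- series_get(series, sp, "gas")
  if (nrow(g) == 0) return(g)
  tt <- series_temperature(series)
  p <- extents$reactor_pressure
  gall <- list(CH4 = series_get(series, "CH4", "gas"),
               CO2 = series_get(series, "CO2", "gas"),
               H2 = series_get(series, "H2", "gas"))
  mass <- ledger_mass(extents$ledger, g$day)
  tot <- vapply(seq_len(nrow(g)), function(i) {
    d <- g$day[i]
    amt <- purrr::map_dbl(gall, ~ if (nrow(.x) == 0) 0 else
      series_interp(.x, d))
    amt[is.na(amt)] <- 0
    y <- amt / sum(amt)
    y <- y[y > 0]
    phi <- pr_fugacity_coefficients(y, tt, p, constants)
    m <- dissolve_gas(sp, y[[sp]] * p * phi[[sp]], tt, constants)
    g$value[i] + m * mass[i]
  }, numeric(1))
  tibble::tibble(day = g$day, value = tot, rel_unc = g$rel_unc)
}

series_interp_or_na <- function(tab, days) {
  if (nrow(tab) == 0) return(rep(NA_real_, length(days)))
  out <- rep(NA_real_, length(days))
  hit <- days %in% tab$day
  out[hit] <- tab$value[match(days[hit], tab$day)]
  out
}

#' @export
print.h2_budget <- function(x, ...) {
  cat("<h2_budget>\n")
  print(x$attribution)
  invisible(x)
}
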