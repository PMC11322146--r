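#' Construct an event timeline
#'
#' The reactor's discrete events in long form: one row per (day, kind,
#' quantity).  Kinds and their quantities:
#'
#' * `gas_injection` / `gas_withdrawal`: `species` is a gas name, `value`
#'   its amount in mol;
#' * `water_addition`: a row with `species = "mass"` giving the added
#'   water mass (kg) plus one row per solute giving the source molality
#'   (mol/kg);
#' * `liquid_withdrawal`: `species = "mass"`, withdrawn mass (kg); solutes
#'   leave at the reactor's current molality;
#' * `piston_move`: `species = "volume"`, new headspace volume (L).
#'
#' @param day,kind,species,value Vectors of equal length (or a data frame
#'   via `events`).
#' @param events Optional data frame with those four columns.
#' @return A tibble of class `event_timeline`, sorted by day.
#' @examples
#' tl <- event_timeline(
#'   day = c(9, 17, 17), kind = c("gas_injection", "water_addition",
#'                                "water_addition"),
#'   species = c("H2", "mass", "so4"), value = c(0.106, 0.353, 7.0e-4)
#' )
#' @export
event_timeline <- function(day = numeric(), kind = character(),
                           species = character(), value = numeric(),
                           events = NULL) {
  if (!is.null(events)) {
    tl <- tibble::as_tibble(events)[c("day", "kind", "species", "value")]
  } else {
    tl <- tibble::tibble(day = day, kind = kind, species = species,
                         value = value)
  }
  kinds <- c("gas_injection", "gas_withdrawal", "water_addition",
             "liquid_withdrawal", "piston_move")
  bad <- setdiff(unique(tl$kind), kinds)
  if (length(bad) > 0) {
    stop("unknown event kind(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(kinds, collapse = ", "), call. = FALSE)
  }
  if (any(tl$value < 0)) stop("event amounts must be >= 0", call. = FALSE)
  if (is.unsorted(tl$day)) tl <- dplyr::arrange(tl, .data$day)
  structure(tl, class = c("event_timeline", class(tl)))
}

#' Water-mass and solute-addition ledger
#'
#' Tracks the reactor water mass and the cumulative solute additions
#' across the event timeline.  The sampling convention is: on a given day,
#' water additions happen before that day's measurement and the routine
#' sampling withdrawal happens after it, so the mass in force at a
#' measurement on day *d* includes all additions up to *d* and all
#' withdrawals strictly before *d*.
#'
#' @param timeline An [event_timeline()].
#' @param initial_mass_kg Water mass at day 0 (kg), > 0.
#' @return A `mass_ledger`: tibble of mass-changing events with the mass
#'   after each, plus an `additions` tibble (day, component, mol) of
#'   solutes entering with added water.  Use [ledger_mass()] to query the
#'   mass at a measurement day.
#' @examples
#' tl <- event_timeline(
#'   day = c(17, 17), kind = c("water_addition", "water_addition"),
#'   species = c("mass", "so4"), value = c(0.353, 7.0e-4)
#' )
#' led <- mass_ledger(tl, initial_mass_kg = 1.85)
#' ledger_mass(led, 21)
#' @export
mass_ledger <- function(timeline, initial_mass_kg) {
  stopifnot(inherits(timeline, "event_timeline"))
  if (!is.finite(initial_mass_kg) || initial_mass_kg <= 0) {
    stop("initial water mass must be > 0", call. = FALSE)
  }
  ev <- dplyr::filter(timeline,
                      .data$kind %in% c("water_addition",
                                        "liquid_withdrawal"))
  mass_ev <- dplyr::filter(ev, .data$species == "mass")
  mass_ev <- dplyr::mutate(
    mass_ev,
    dmass = ifelse(.data$kind == "water_addition", .data$value,
                   -.data$value),
    mass_after = initial_mass_kg + cumsum(.data$dmass)
  )
  if (any(mass_ev$mass_after <= 0)) {
    bad <- mass_ev[which(mass_ev$mass_after <= 0)[1], ]
    stop("water mass would drop to ", signif(bad$mass_after, 3),
         " kg after the ", bad$kind, " of ", bad$value, " kg on day ",
         bad$day, call. = FALSE)
  }

  add <- dplyr::filter(ev, .data$kind == "water_addition",
                       .data$species != "mass")
  if (nrow(add) > 0) {
    masses <- stats::setNames(
      mass_ev$value[mass_ev$kind == "water_addition"],
      mass_ev$day[mass_ev$kind == "water_addition"])
    add <- dplyr::mutate(
      add, mol = unname(.data$value * masses[as.character(.data$day)]))
    additions <- dplyr::select(add, day = "day", component = "species",
                               mol = "mol")
  } else {
    additions <- tibble::tibble(day = numeric(), component = character(),
                                mol = numeric())
  }
  structure(
    list(initial_mass_kg = initial_mass_kg,
         events = mass_ev[c("day", "kind", "dmass", "mass_after")],
         additions = additions,
         timeline = timeline),
    class = "mass_ledger"
  )
}

#' @rdname mass_ledger
#' @param ledger A `mass_ledger`.
#' @param day Measurement day(s).
#' @return `ledger_mass()`: water mass (kg) in force at the measurement of
#'   each `day`.
#' @export
ledger_mass <- function(ledger, day) {
  vapply(day, function(d) {
    ev <- ledger$events
    keep <- (ev$kind == "water_addition" & ev$day <= d) |
      (ev$kind == "liquid_withdrawal" & ev$day < d)
    ledger$initial_mass_kg + sum(ev$dmass[keep])
  }, numeric(1))
}

# solute moles added on days in (t1, t2] for one component
ledger_added <- function(ledger, component, t1, t2) {
  a <- ledger$additions
  sum(a$mol[a$component == component & a$day > t1 & a$day <= t2])
}

# withdrawal events with day in [t1, t2) (a day-t1 sampling withdrawal
# happens after the t1 measurement, inside the following interval)
ledger_withdrawals <- function(ledger, t1, t2) {
  ev <- ledger$events
  ev[ev$kind == "liquid_withdrawal" & ev$day >= t1 & ev$day < t2,
     c("day", "dmass")]
}

#' @export
print.mass_ledger <- function(x, ...) {
  cat("<mass_ledger> initial", x$initial_mass_kg, "kg,",
      nrow(x$events), "mass events,", nrow(x$additions),
      "solute additions\n")
  print(x$events)
  invisible(x)
}
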