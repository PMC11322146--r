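#' Construct an aqueous solution from component totals
#'
#' An aqueous solution is described by its water mass, temperature and
#' component *totals* on the molality scale (mol/kg water).  Dissolved
#' inorganic carbon (`dic`) and dissolved sulfide (`sulfide`) are totals to
#' be distributed over their acid-base species by [speciate()]; all other
#' components are carried as conservative ions (acetate and formate are
#' treated as fully dissociated anions — their pKa of 4.8 and 3.8 make the
#' protonated fraction negligible above pH 5.5).
#'
#' @param mass_kg Water mass (kg), > 0.
#' @param temperature Temperature (K).
#' @param dic Total dissolved inorganic carbon: CO2(aq) + HCO3- + CO3--.
#' @param sulfide Total dissolved sulfide: H2S(aq) + HS-.
#' @param na,k,ca,mg,cl,so4,acetate,formate,fe,ba Conservative component
#'   totals (mol/kg).  Iron and barium are carried as divalent cations.
#' @param h2,ch4 Dissolved neutral gas molalities (mol/kg).
#' @param charge_offset Permanent charge imbalance of the water
#'   (eq/kg, cations minus anions) carried through every speciation; this is
#'   how the analytic imbalance of a measured water is represented instead
#'   of being zeroed by adjusting an ion.
#' @return A tibble of class `aqueous_solution` with one row per component.
#' @examples
#' w <- formation_water()
#' speciate(w)
#' @export
aqueous_solution <- function(mass_kg = 1, temperature = 298.15,
                             dic = 0, sulfide = 0, na = 0, k = 0, ca = 0,
                             mg = 0, cl = 0, so4 = 0, acetate = 0,
                             formate = 0, fe = 0, ba = 0, h2 = 0, ch4 = 0,
                             charge_offset = 0) {
  tot <- c(dic = dic, sulfide = sulfide, na = na, k = k, ca = ca, mg = mg,
           cl = cl, so4 = so4, acetate = acetate, formate = formate,
           fe = fe, ba = ba, h2 = h2, ch4 = ch4)
  if (!is.finite(mass_kg) || mass_kg <= 0) {
    stop("water mass must be > 0", call. = FALSE)
  }
  if (any(!is.finite(tot))) stop("component totals must be finite",
                                 call. = FALSE)
  if (any(tot < 0)) {
    bad <- names(tot)[tot < 0]
    stop("negative component total(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(component = names(tot), molality = unname(tot))
  structure(out, class = c("aqueous_solution", class(out)),
            mass_kg = mass_kg, temperature = temperature,
            charge_offset = charge_offset)
}

solution_totals <- function(solution) {
  stats::setNames(solution$molality, solution$component)
}

# rebuild a solution with some totals replaced
solution_update <- function(solution, ...) {
  repl <- list(...)
  tot <- solution_totals(solution)
  tot[names(repl)] <- unlist(repl)
  do.call(aqueous_solution, c(
    as.list(tot),
    list(mass_kg = attr(solution, "mass_kg"),
         temperature = attr(solution, "temperature"),
         charge_offset = attr(solution, "charge_offset"))
  ))
}

#' Reference waters of the studied storage aquifer
#'
#' `formation_water()` is the raw formation water as analysed at the
#' wellhead (field pH 8.3); `mixed_water()` is the reactor's initial liquid
#' charge (the mix of bottom-hole and filtered wellhead samples) as analysed
#' just before injection.  The two analyses are deliberately kept separate:
#' they were made on different samples and do not reconcile exactly.
#'
#' @param mass_kg Water mass (kg).
#' @param temperature Temperature (K).
#' @return An [aqueous_solution()].
#' @export
formation_water <- function(mass_kg = 1, temperature = 298.15) {
  aqueous_solution(
    mass_kg = mass_kg, temperature = temperature,
    dic = 3.44e-3, ca = 1.37e-3, mg = 0.30e-3, na = 0.50e-3, k = 0.15e-3,
    cl = 0.23e-3, so4 = 0.09e-3, fe = 9.24e-6
  )
}

#' @rdname formation_water
#' @export
mixed_water <- function(mass_kg = 1.85, temperature = 309.15) {
  aqueous_solution(
    mass_kg = mass_kg, temperature = temperature,
    dic = 2.4e-3, ca = 1.31e-3, na = 6.0e-4, mg = 4.4e-4, cl = 3.0e-4,
    so4 = 7.0e-4, fe = 6.5e-6, ba = 1.0e-6
  )
}
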