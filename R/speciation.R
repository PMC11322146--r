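# Aqueous speciation: carbonate and sulfide acid-base systems, optional
# Ca/Mg ion pairs, Davies activity corrections, pH closed on charge balance.
#
# The workhorse aq_eval() evaluates every mass-action law at a given pH and
# iterates ionic strength (and water activity) to self-consistency; the
# public speciate() wraps a root solve of the charge balance around it.

# Evaluate the full species distribution at a fixed pH.
#
# tot: named vector of component totals (see aqueous_solution components).
# co2_aq: if non-NULL, "open" mode — the free CO2(aq) molality is imposed
#   (gas-buffered) and dic becomes an output instead of a constraint.
aq_eval <- function(pH, tot, temperature, constants = default_constants(),
                    ion_pairs = TRUE, co2_aq = NULL) {
  TT <- temperature
  K1 <- 10^log_k(constants, "carbonic_1", TT)
  K2 <- 10^log_k(constants, "carbonic_2", TT)
  Kw <- 10^log_k(constants, "water", TT)
  Ks <- 10^log_k(constants, "h2s_1", TT)
  Ksp <- 10^log_k(constants, "calcite", TT)
  Kp_cahco3 <- 10^log_k(constants, "ca_hco3", TT)
  Kp_mghco3 <- 10^log_k(constants, "mg_hco3", TT)
  Kp_caso4 <- 10^log_k(constants, "ca_so4", TT)

  open_co2 <- !is.null(co2_aq)
  aH <- 10^(-pH)
  I <- 0.5 * sum(c(1, 1, 4, 4, 1, 4, 1, 1, 4, 4) *
                   tot[c("na", "k", "ca", "mg", "cl", "so4", "acetate",
                         "formate", "fe", "ba")]) +
    0.5 * tot[["dic"]]
  I <- min(max(I, 0), constants$davies$max_ionic_strength)
  aw <- 1
  m <- NULL

  for (iter in 1:80) {
    g1 <- activity_coefficient(1, I, TT, constants)
    g2 <- activity_coefficient(2, I, TT, constants)

    mH <- aH / g1
    mOH <- Kw / (aw * aH) / g1                       # H2O = H+ + OH-
    r1 <- K1 * aw / (aH * g1)                        # mHCO3/mCO2
    r2 <- K2 * g1 / (aH * g2)                        # mCO3/mHCO3

    # ion-pair / free-ion fixed point
    ca_f <- tot[["ca"]]; mg_f <- tot[["mg"]]; so4_f <- tot[["so4"]]
    co2_f <- if (open_co2) co2_aq else tot[["dic"]] / (1 + r1 + r1 * r2)
    for (k in 1:40) {
      denom_pair <- if (ion_pairs) {
        r1 * (Kp_cahco3 * g2 * ca_f + Kp_mghco3 * g2 * mg_f)
      } else 0
      co2_new <- if (open_co2) co2_aq else {
        tot[["dic"]] / (1 + r1 + r1 * r2 + denom_pair)
      }
      mHCO3 <- co2_new * r1
      if (ion_pairs) {
        ca_new <- tot[["ca"]] / (1 + Kp_cahco3 * g2 * mHCO3 +
                                   Kp_caso4 * g2 * g2 * so4_f)
        mg_new <- tot[["mg"]] / (1 + Kp_mghco3 * g2 * mHCO3)
        so4_new <- tot[["so4"]] / (1 + Kp_caso4 * g2 * g2 * ca_new)
      } else {
        ca_new <- tot[["ca"]]; mg_new <- tot[["mg"]]; so4_new <- tot[["so4"]]
      }
      done <- max(abs(c(co2_new - co2_f, ca_new - ca_f, mg_new - mg_f,
                        so4_new - so4_f))) < 1e-18
      co2_f <- co2_new; ca_f <- ca_new; mg_f <- mg_new; so4_f <- so4_new
      if (done) break
    }
    mHCO3 <- co2_f * r1
    mCO3 <- mHCO3 * r2
    m_cahco3 <- if (ion_pairs) Kp_cahco3 * g2 * ca_f * mHCO3 else 0
    m_mghco3 <- if (ion_pairs) Kp_mghco3 * g2 * mg_f * mHCO3 else 0
    m_caso4 <- if (ion_pairs) Kp_caso4 * g2 * g2 * ca_f * so4_f else 0

    rs <- Ks / (aH * g1)                             # mHS/mH2S
    mH2S <- tot[["sulfide"]] / (1 + rs)
    mHS <- mH2S * rs

    m <- c(
      "H+" = mH, "OH-" = mOH,
      "CO2(aq)" = co2_f, "HCO3-" = mHCO3, "CO3--" = mCO3,
      "H2S(aq)" = mH2S, "HS-" = mHS,
      "Ca++" = ca_f, "Mg++" = mg_f, "SO4--" = so4_f,
      "CaHCO3+" = m_cahco3, "MgHCO3+" = m_mghco3, "CaSO4(aq)" = m_caso4,
      "Na+" = tot[["na"]], "K+" = tot[["k"]], "Cl-" = tot[["cl"]],
      "CH3COO-" = tot[["acetate"]], "HCOO-" = tot[["formate"]],
      "Fe++" = tot[["fe"]], "Ba++" = tot[["ba"]],
      "H2(aq)" = tot[["h2"]], "CH4(aq)" = tot[["ch4"]]
    )
    z <- c(1, -1, 0, -1, -2, 0, -1, 2, 2, -2, 1, 1, 0,
           1, 1, -1, -1, -1, 2, 2, 0, 0)

    I_new <- min(0.5 * sum(z^2 * m), constants$davies$max_ionic_strength)
    aw_new <- water_activity(sum(m))
    if (abs(I_new - I) < 1e-14 && abs(aw_new - aw) < 1e-12) {
      I <- I_new; aw <- aw_new
      break
    }
    I <- I_new; aw <- aw_new
  }

  g <- ifelse(z == 0, 1, activity_coefficient(abs(z), I, TT, constants))
  names(g) <- names(m)
  # pH is defined on the activity scale: a(H+) = 10^-pH exactly
  a <- g * m
  a[["H+"]] <- aH
  a[["OH-"]] <- Kw / (aw * aH)

  imbalance <- sum(z * m)
  dic <- m[["CO2(aq)"]] + m[["HCO3-"]] + m[["CO3--"]] +
    m[["CaHCO3+"]] + m[["MgHCO3+"]]
  si_calcite <- if (a[["Ca++"]] > 0 && a[["CO3--"]] > 0) {
    log10(a[["Ca++"]] * a[["CO3--"]] / Ksp)
  } else -Inf

  list(molality = m, gamma = g, activity = a, charge = z,
       imbalance = unname(imbalance), ionic_strength = unname(I),
       water_activity = aw, dic = unname(dic),
       si_calcite = unname(si_calcite), pH = unname(pH))
}

#' Speciate a closed aqueous solution
#'
#' Distributes the component totals of an [aqueous_solution()] over the
#' carbonate (CO2(aq)/HCO3-/CO3--) and sulfide (H2S(aq)/HS-) acid-base
#' systems, with pH as the charge-balance closure variable: the solver finds
#' the pH at which the net ionic charge equals the solution's permanent
#' `charge_offset` (zero for an electroneutral water).  Activity
#' coefficients come from the Davies equation and are iterated to
#' self-consistency with the ionic strength; the CaHCO3+, MgHCO3+ and
#' CaSO4(aq) ion pairs are included by default.
#'
#' @param solution An [aqueous_solution()].
#' @param constants A [thermo_constants()] object.
#' @param ion_pairs Include the Ca/Mg ion pairs (default TRUE).
#' @param pH If supplied, no charge-balance solve is done: the species
#'   distribution is evaluated at this fixed pH and the resulting charge
#'   imbalance is reported as-is.
#' @return An object of class `speciation`: pH, ionic strength (mol/kg),
#'   calcite saturation index, charge imbalance (eq/kg), water activity and
#'   a per-species table of molality, activity coefficient and activity.
#'   [tidy()][generics::tidy] returns the species table, [glance()]
#'   [generics::glance] the scalar summary.
#' @examples
#' speciate(aqueous_solution(dic = 5e-3, ca = 2e-3, temperature = 309.15))
#' @export
speciate <- function(solution, constants = default_constants(),
                     ion_pairs = TRUE, pH = NULL) {
  stopifnot(inherits(solution, "aqueous_solution"))
  tot <- solution_totals(solution)
  TT <- attr(solution, "temperature")
  offset <- attr(solution, "charge_offset")

  if (is.null(pH)) {
    fn <- function(p) {
      aq_eval(p, tot, TT, constants, ion_pairs)$imbalance - offset
    }
    lo <- fn(0); hi <- fn(14)
    if (is.na(lo) || is.na(hi) || sign(lo) == sign(hi)) {
      stop("charge balance cannot be closed in 0 < pH < 14 ",
           "(residual at pH 0: ", signif(lo, 3), ", at pH 14: ",
           signif(hi, 3), " eq/kg)", call. = FALSE)
    }
    pH <- stats::uniroot(fn, c(0, 14), tol = 1e-13)$root
  }
  ev <- aq_eval(pH, tot, TT, constants, ion_pairs)

  species <- tibble::tibble(
    species = names(ev$molality),
    charge = ev$charge,
    molality = unname(ev$molality),
    gamma = unname(ev$gamma),
    activity = unname(ev$activity)
  )
  structure(
    list(pH = ev$pH, ionic_strength = ev$ionic_strength,
         si_calcite = ev$si_calcite,
         charge_imbalance = ev$imbalance,
         water_activity = ev$water_activity,
         dic = ev$dic, temperature = TT,
         species = species, totals = tot,
         mass_kg = attr(solution, "mass_kg"),
         constants_version = constants$version),
    class = "speciation"
  )
}

#' @export
print.speciation <- function(x, digits = 4, ...) {
  cat("<speciation>  pH", format(x$pH, digits = digits),
      " I", format(x$ionic_strength, digits = 3), "mol/kg",
      " SI(calcite)", format(x$si_calcite, digits = 3),
      " imbalance", format(x$charge_imbalance, digits = 3), "eq/kg\n")
  print(dplyr::filter(x$species, .data$molality > 0))
  invisible(x)
}

# activity of a named species from a speciation result (errors if absent)
species_activity <- function(speciation, species) {
  i <- match(species, speciation$species$species)
  if (is.na(i)) {
    stop("species '", species, "' not present in speciation result",
         call. = FALSE)
  }
  speciation$species$activity[i]
}

#' Distribution of dissolved sulfide between H2S(aq) and HS-
#'
#' Returns the mole fractions of the two sulfide species at the given pH,
#' evaluated on the activity scale (pK of the first sulfide dissociation at
#' the requested temperature, molalities corrected by the Davies activity
#' coefficient at the supplied ionic strength).  These fractions are the
#' pH-dependent stoichiometric coefficients of sulfide in the
#' sulfate-reduction scheme.
#'
#' @param pH pH (0 < pH < 14).
#' @param temperature Temperature (K).
#' @param ionic_strength Ionic strength used for the HS- activity
#'   correction (mol/kg); 0 gives the infinite-dilution split.
#' @param constants A [thermo_constants()] object.
#' @return Named vector `c(x_h2s = , x_hs = )` summing to 1 exactly.
#' @examples
#' sulfide_split(6.0, 298.15)
#' @export
sulfide_split <- function(pH, temperature = 298.15, ionic_strength = 0,
                          constants = default_constants()) {
  if (!is.finite(pH) || pH <= 0 || pH >= 14) {
    stop("pH must lie strictly between 0 and 14", call. = FALSE)
  }
  Ks <- 10^log_k(constants, "h2s_1", temperature)
  g1 <- activity_coefficient(1, ionic_strength, temperature, constants)
  r <- Ks / (10^(-pH) * g1)          # mHS / mH2S
  x_hs <- r / (1 + r)
  c(x_h2s = 1 - x_hs, x_hs = x_hs)
}
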