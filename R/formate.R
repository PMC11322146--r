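# Formate equilibrium thermodynamics: standard Gibbs energy of the
# hydrogenotrophic formate-production reaction HCO3- + H2(aq) -> HCOO- +
# H2O from tabulated formation data, Gibbs-Helmholtz temperature
# correction, equilibrium constant, and the equilibrium formate molality
# implied by the dissolved H2 and bicarbonate activities.

#' Standard Gibbs energy of reaction from formation data
#'
#' `sum(nu_i * DeltaGf0_i)` at the reference state (298.15 K, 1 bar) using
#' the formation entries pinned in the constants file.
#'
#' @param nu Named stoichiometric vector (reactants negative), names being
#'   formation-data species such as `"HCO3-"`, `"H2(aq)"`, `"HCOO-"`,
#'   `"H2O(l)"`; a [reaction_scheme()] may be given instead.
#' @param constants A [thermo_constants()] object.
#' @return Standard Gibbs energy of reaction (kJ/mol).
#' @examples
#' delta_g_reaction(c("HCO3-" = -1, "H2(aq)" = -1, "HCOO-" = 1,
#'                    "H2O(l)" = 1))
#' @export
delta_g_reaction <- function(nu, constants = default_constants()) {
  if (inherits(nu, "reaction_scheme")) nu <- nu$nu
  sum(vapply(seq_along(nu), function(i) {
    nu[[i]] * formation_data(constants, names(nu)[i])$gf
  }, numeric(1)))
}

#' @rdname delta_g_reaction
#' @return `delta_h_reaction()`: standard reaction enthalpy (kJ/mol).
#' @export
delta_h_reaction <- function(nu, constants = default_constants()) {
  if (inherits(nu, "reaction_scheme")) nu <- nu$nu
  sum(vapply(seq_along(nu), function(i) {
    nu[[i]] * formation_data(constants, names(nu)[i])$hf
  }, numeric(1)))
}

#' Gibbs-Helmholtz temperature correction
#'
#' Integrated Gibbs-Helmholtz relation with a temperature-independent
#' reaction enthalpy:
#' `dG(T)/T = dG(Tref)/Tref + dH * (1/T - 1/Tref)`.
#'
#' @param dg_tref Standard reaction Gibbs energy at `tref` (kJ/mol).
#' @param dh Standard reaction enthalpy (kJ/mol).
#' @param temperature Target temperature (K), > 0.
#' @param tref Reference temperature (K), > 0.
#' @return Standard reaction Gibbs energy at `temperature` (kJ/mol).
#' @examples
#' gibbs_helmholtz(-18.959, -15.24, 309.15)
#' @export
gibbs_helmholtz <- function(dg_tref, dh, temperature, tref = 298.15) {
  stopifnot(temperature > 0, tref > 0)
  temperature * (dg_tref / tref + dh * (1 / temperature - 1 / tref))
}

#' Reaction thermodynamics of a scheme at temperature
#'
#' Bundles the standard Gibbs energy at the reference temperature, the
#' standard enthalpy, the Gibbs-Helmholtz-corrected Gibbs energy and the
#' equilibrium constant `K(T) = exp(-dG(T)/RT)` (so a spontaneous reaction
#' has K > 1).
#'
#' @param nu Named stoichiometric vector or [reaction_scheme()].
#' @param temperature Temperature (K).
#' @param constants A [thermo_constants()] object.
#' @return A `reaction_thermo` object with fields `dg_tref`, `dh`, `dg_t`,
#'   `K`, `temperature`, `tref`.
#' @examples
#' th <- reaction_thermo(formate_scheme_nu(), 309.15)
#' th$K
#' @export
reaction_thermo <- function(nu, temperature, constants = default_constants()) {
  if (inherits(nu, "reaction_scheme")) nu <- nu$nu
  dg <- delta_g_reaction(nu, constants)
  dh <- delta_h_reaction(nu, constants)
  dgt <- gibbs_helmholtz(dg, dh, temperature, constants$tref)
  K <- exp(-dgt * 1000 / (constants$R * temperature))
  structure(list(nu = nu, dg_tref = dg, dh = dh, dg_t = dgt, K = K,
                 temperature = temperature, tref = constants$tref),
            class = "reaction_thermo")
}

#' @export
print.reaction_thermo <- function(x, ...) {
  cat("<reaction_thermo>\n")
  cat("  dG0(", x$tref, "K) =", format(x$dg_tref, digits = 5), "kJ/mol\n")
  cat("  dH0           =", format(x$dh, digits = 5), "kJ/mol\n")
  cat("  dG0(", x$temperature, "K) =", format(x$dg_t, digits = 5),
      "kJ/mol\n")
  cat("  K(", x$temperature, "K)  =", format(x$K, digits = 5), "\n")
  invisible(x)
}

#' @rdname reaction_thermo
#' @return `formate_scheme_nu()`: the stoichiometric vector of formate
#'   production, `HCO3- + H2(aq) -> HCOO- + H2O`.
#' @export
formate_scheme_nu <- function() {
  c("HCO3-" = -1, "H2(aq)" = -1, "HCOO-" = 1, "H2O(l)" = 1)
}

#' Dissolved-H2 activity from a headspace composition
#'
#' The activity of dissolved H2 in equilibrium with a headspace containing
#' mole fraction `y_h2` at total pressure `pressure`.  With
#' `method = "partial_pressure"` (default) Henry's law is applied to the
#' H2 partial pressure; `"fugacity"` first corrects the partial pressure
#' by the Peng-Robinson fugacity coefficient of H2 in the full mixture
#' (`composition` must then be given, or a CH4-dominated headspace is
#' assumed).  The default avoids compounding the unparameterised (k_ij =
#' 0) equation-of-state correction for H2 into the thermodynamic chain;
#' both paths are exposed because published treatments differ.
#'
#' @param y_h2 H2 mole fraction in the headspace.
#' @param pressure Total pressure (bar).
#' @param temperature Temperature (K).
#' @param method `"partial_pressure"` or `"fugacity"`.
#' @param composition Full headspace composition for the fugacity path.
#' @param constants A [thermo_constants()] object.
#' @return Activity of H2(aq) (equal to its molality; the neutral species
#'   has unit activity coefficient).
#' @examples
#' dissolved_h2_activity(0.022, 60, 309.15)
#' @export
dissolved_h2_activity <- function(y_h2, pressure, temperature,
                                  method = c("partial_pressure",
                                             "fugacity"),
                                  composition = NULL,
                                  constants = default_constants()) {
  method <- match.arg(method)
  f <- if (method == "partial_pressure") {
    y_h2 * pressure
  } else {
    if (is.null(composition)) {
      composition <- c(CH4 = 1 - y_h2, H2 = y_h2)
    }
    phi <- pr_fugacity_coefficients(composition, temperature, pressure,
                                    constants)
    y_h2 * pressure * phi[["H2"]]
  }
  dissolve_gas("H2", f, temperature, constants)
}

#' Equilibrium formate molality
#'
#' Formate molality at thermodynamic equilibrium with dissolved H2 and
#' bicarbonate by the formate-production mass-action law:
#' `a(HCOO-) = K(T) a(H2) a(HCO3-) / a(H2O)`, converted to molality with
#' the formate activity coefficient.  When a [speciate()] result is given,
#' the bicarbonate and water activities and the formate activity
#' coefficient are taken from it.
#'
#' @param a_h2 Dissolved-H2 activity (see [dissolved_h2_activity()]), > 0.
#' @param speciation Optional [speciate()] result supplying `a_hco3`,
#'   `a_h2o` and `gamma_formate`.
#' @param a_hco3 Bicarbonate activity (required if no speciation given).
#' @param temperature Temperature (K).
#' @param a_h2o Water activity (default 1).
#' @param gamma_formate Formate activity coefficient (default: equal to
#'   the bicarbonate coefficient, as both are singly charged).
#' @param constants A [thermo_constants()] object.
#' @return A tibble with `K`, the equilibrium formate activity and
#'   molality (mol/kg).
#' @examples
#' a_h2 <- dissolved_h2_activity(0.022, 60, 309.15)
#' formate_equilibrium(a_h2, a_hco3 = 4.4e-3, temperature = 309.15)
#' @export
formate_equilibrium <- function(a_h2, speciation = NULL, a_hco3 = NULL,
                                temperature = NULL, a_h2o = NULL,
                                gamma_formate = NULL,
                                constants = default_constants()) {
  if (!is.null(speciation)) {
    if (is.null(a_hco3)) a_hco3 <- species_activity(speciation, "HCO3-")
    if (is.null(a_h2o)) a_h2o <- speciation$water_activity
    if (is.null(temperature)) temperature <- speciation$temperature
    if (is.null(gamma_formate)) {
      i <- match("HCOO-", speciation$species$species)
      gamma_formate <- speciation$species$gamma[i]
    }
  }
  if (is.null(a_h2o)) a_h2o <- 1
  if (is.null(gamma_formate)) {
    gamma_formate <- 1
  }
  if (is.null(a_hco3) || is.null(temperature)) {
    stop("a_hco3 and temperature are required (directly or via a ",
         "speciation)", call. = FALSE)
  }
  if (a_h2 < 0 || a_hco3 <= 0 || a_h2o <= 0) {
    stop("a(HCO3-) and a(H2O) must be > 0 and a(H2) >= 0", call. = FALSE)
  }
  th <- reaction_thermo(formate_scheme_nu(), temperature, constants)
  act <- th$K * a_h2 * a_hco3 / a_h2o
  tibble::tibble(
    K = th$K, dg_t = th$dg_t, temperature = temperature,
    a_h2 = a_h2, a_hco3 = a_hco3,
    formate_activity = act,
    formate_molality = act / gamma_formate
  )
}
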