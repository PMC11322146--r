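# Peng-Robinson equation of state for the reactor headspace
# (CH4/CO2/H2/N2/H2S mixtures, van der Waals mixing rules, k_ij = 0 by
# default).  Units: K, bar, L/mol.  R in L bar / mol / K:

RGAS_LBAR <- 0.0831446

# per-species a(T), b
pr_pure <- function(species, temperature, constants) {
  g <- constants$gases[[species]]
  if (is.null(g)) {
    stop("no Peng-Robinson parameters for gas '", species,
         "' in constants file", call. = FALSE)
  }
  kappa <- 0.37464 + 1.54226 * g$omega - 0.26992 * g$omega^2
  alpha <- (1 + kappa * (1 - sqrt(temperature / g$tc)))^2
  c(a = 0.45724 * RGAS_LBAR^2 * g$tc^2 / g$pc * alpha,
    b = 0.07780 * RGAS_LBAR * g$tc / g$pc)
}

# mixture a, b and the composition-weighted cross sums; binary interaction
# parameters k_ij default to 0 and may be pinned in the constants file as
# kij entries named "A:B"
pr_mixture <- function(composition, temperature, constants) {
  sps <- names(composition)
  ab <- vapply(sps, pr_pure, numeric(2), temperature = temperature,
               constants = constants)
  ai <- ab["a", ]; bi <- ab["b", ]
  names(ai) <- names(bi) <- sps
  sqa <- sqrt(ai)
  k <- matrix(0, length(sps), length(sps), dimnames = list(sps, sps))
  for (nm in names(constants$kij)) {
    pair <- strsplit(nm, ":", fixed = TRUE)[[1]]
    if (all(pair %in% sps)) {
      k[pair[1], pair[2]] <- k[pair[2], pair[1]] <- constants$kij[[nm]]
    }
  }
  across <- outer(sqa, sqa) * (1 - k)
  amix <- drop(composition %*% across %*% composition)
  # per-species sum_j y_j a_ij, needed for ln phi
  asum <- drop(across %*% composition)
  list(ai = ai, bi = bi, a = amix, b = sum(composition * bi), asum = asum)
}

pr_vapor_z <- function(A, B) {
  cf <- c(-(A * B - B^2 - B^3), A - 3 * B^2 - 2 * B, -(1 - B), 1)
  r <- polyroot(cf)
  zr <- Re(r)[abs(Im(r)) < 1e-8]
  zr <- zr[zr > B]
  if (length(zr) == 0) {
    stop("Peng-Robinson cubic has no physical vapor root at these ",
         "conditions", call. = FALSE)
  }
  max(zr)  # vapor root: the reactor headspace never enters the 2-phase dome
}

check_composition <- function(composition) {
  if (is.null(names(composition)) || any(!nzchar(names(composition)))) {
    stop("composition must be a named vector of mole fractions",
         call. = FALSE)
  }
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-8) {
    stop("mole fractions must be >= 0 and sum to 1", call. = FALSE)
  }
  invisible(composition)
}

#' Molar volume of a gas mixture (Peng-Robinson)
#'
#' Solves the Peng-Robinson cubic for the vapor root (largest real root)
#' with van der Waals mixing rules; binary interaction parameters default
#' to zero.
#'
#' @param composition Named vector of mole fractions (names are gas species
#'   present in the constants file), summing to 1.
#' @param temperature Temperature (K), > 0.
#' @param pressure Pressure (bar), > 0.
#' @param constants A [thermo_constants()] object.
#' @return Molar volume (L/mol).
#' @examples
#' pr_molar_volume(c(CH4 = 0.978, H2 = 0.022), 309.15, 60)
#' @export
pr_molar_volume <- function(composition, temperature, pressure,
                            constants = default_constants()) {
  check_composition(composition)
  stopifnot(temperature > 0, pressure > 0)
  m <- pr_mixture(composition, temperature, constants)
  A <- m$a * pressure / (RGAS_LBAR * temperature)^2
  B <- m$b * pressure / (RGAS_LBAR * temperature)
  pr_vapor_z(A, B) * RGAS_LBAR * temperature / pressure
}

#' Fugacity coefficients of a gas mixture (Peng-Robinson)
#'
#' Standard Peng-Robinson fugacity-coefficient expression evaluated at the
#' vapor root.  All coefficients tend to 1 as pressure tends to 0.
#'
#' @inheritParams pr_molar_volume
#' @return Named vector of dimensionless fugacity coefficients, one per
#'   species of `composition`.  The fugacity of species i is
#'   `y_i * P * phi_i`.
#' @examples
#' pr_fugacity_coefficients(c(CH4 = 0.973, CO2 = 0.005, H2 = 0.022),
#'                          309.15, 60)
#' @export
pr_fugacity_coefficients <- function(composition, temperature, pressure,
                                     constants = default_constants()) {
  check_composition(composition)
  stopifnot(temperature > 0, pressure > 0)
  m <- pr_mixture(composition, temperature, constants)
  A <- m$a * pressure / (RGAS_LBAR * temperature)^2
  B <- m$b * pressure / (RGAS_LBAR * temperature)
  Z <- pr_vapor_z(A, B)
  lnphi <- m$bi / m$b * (Z - 1) - log(Z - B) -
    A / (2 * sqrt(2) * B) * (2 * m$asum / m$a - m$bi / m$b) *
    log((Z + (1 + sqrt(2)) * B) / (Z + (1 - sqrt(2)) * B))
  exp(lnphi)
}

# pressure from molar volume (explicit in the PR form); used by the
# fixed-volume equilibration where V is the known quantity
pr_pressure <- function(composition, temperature, molar_volume,
                        constants = default_constants()) {
  m <- pr_mixture(composition, temperature, constants)
  RGAS_LBAR * temperature / (molar_volume - m$b) -
    m$a / (molar_volume^2 + 2 * m$b * molar_volume - m$b^2)
}

#' Construct a gas-phase state
#'
#' @param ... Named per-species amounts (mol), e.g. `CH4 = 4.54`.
#' @param temperature Temperature (K).
#' @param pressure Pressure (bar); if `NULL` it is computed from `volume`.
#' @param volume Headspace volume (L); if `NULL` it is computed from
#'   `pressure`.
#' @param ideal Use the ideal-gas law instead of Peng-Robinson.
#' @param constants A [thermo_constants()] object.
#' @return A `gas_phase` object: amounts, mole fractions, pressure, volume,
#'   molar volume and per-species fugacities (bar).
#' @examples
#' gas_phase(CH4 = 4.54, CO2 = 4.58e-2, temperature = 309.15, pressure = 62)
#' @export
gas_phase <- function(..., temperature, pressure = NULL, volume = NULL,
                      ideal = FALSE, constants = default_constants()) {
  n <- c(...)
  if (any(n < 0)) stop("gas amounts must be >= 0", call. = FALSE)
  if (is.null(pressure) && is.null(volume)) {
    stop("one of pressure or volume must be given", call. = FALSE)
  }
  if (sum(n) <= 0) stop("gas phase needs a positive total amount",
                        call. = FALSE)
  y <- n / sum(n)
  if (ideal) {
    if (is.null(pressure)) pressure <- sum(n) * RGAS_LBAR * temperature / volume
    vm <- RGAS_LBAR * temperature / pressure
    phi <- stats::setNames(rep(1, length(y)), names(y))
  } else {
    if (is.null(pressure)) {
      pressure <- pr_pressure(y, temperature, volume / sum(n), constants)
    }
    vm <- pr_molar_volume(y, temperature, pressure, constants)
    phi <- pr_fugacity_coefficients(y, temperature, pressure, constants)
  }
  if (is.null(volume)) volume <- vm * sum(n)
  structure(
    list(amounts = n, fractions = y, temperature = temperature,
         pressure = pressure, volume = volume, molar_volume = vm,
         phi = phi, fugacities = y * pressure * phi, ideal = ideal),
    class = "gas_phase"
  )
}

#' @export
print.gas_phase <- function(x, ...) {
  cat("<gas_phase> ", format(x$pressure, digits = 4), "bar,",
      format(x$temperature, digits = 5), "K,",
      format(x$volume, digits = 4), "L\n")
  print(tibble::tibble(species = names(x$amounts),
                       mol = unname(x$amounts),
                       fraction = unname(x$fractions),
                       fugacity_bar = unname(x$fugacities[names(x$amounts)])))
  invisible(x)
}

#' Henry-law dissolution of a gas
#'
#' Molality of the dissolved neutral species in equilibrium with the given
#' fugacity: `m = KH(T) * f`.  Speciation of the dissolved gas beyond the
#' neutral species (e.g. HCO3- from CO2) is the speciation solver's job.
#'
#' @param species Gas species name.
#' @param fugacity Fugacity (bar), >= 0.
#' @param temperature Temperature (K).
#' @param constants A [thermo_constants()] object.
#' @return Molality (mol/kg).
#' @examples
#' dissolve_gas("CO2", 0.31, 309.15)
#' @export
dissolve_gas <- function(species, fugacity, temperature,
                         constants = default_constants()) {
  if (any(fugacity < 0)) stop("fugacity must be >= 0", call. = FALSE)
  henry_constant(constants, species, temperature) * fugacity
}
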