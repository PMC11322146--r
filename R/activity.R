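#' Davies-equation activity coefficient
#'
#' Single-ion activity coefficients from the Davies equation,
#' `log10(gamma) = -A z^2 (sqrt(I)/(1 + sqrt(I)) - 0.3 I)`, the standard
#' low-salinity model (valid to roughly 0.5 mol/kg ionic strength).
#' Neutral species are returned as 1 (the Setchenow salting-out term is
#' negligible at the ionic strengths of a low-salinity aquifer and is not
#' applied).
#'
#' @param charge Integer ionic charge (vectorised).
#' @param ionic_strength Ionic strength (mol/kg), scalar.
#' @param temperature Temperature (K).
#' @param constants A [thermo_constants()] object.
#' @return Activity coefficient(s), dimensionless.
#' @examples
#' activity_coefficient(-1, 0.01, 298.15)
#' @export
activity_coefficient <- function(charge, ionic_strength, temperature = 298.15,
                                 constants = default_constants()) {
  if (!is.finite(ionic_strength) || ionic_strength < 0) {
    stop("ionic strength must be finite and >= 0", call. = FALSE)
  }
  if (ionic_strength > constants$davies$max_ionic_strength) {
    stop("ionic strength ", signif(ionic_strength, 4),
         " mol/kg exceeds the Davies-equation validity domain (",
         constants$davies$max_ionic_strength,
         " mol/kg); refusing to extrapolate", call. = FALSE)
  }
  A <- davies_a(temperature, constants)
  s <- sqrt(ionic_strength)
  10^(-A * charge^2 * (s / (1 + s) - constants$davies$linear_term *
                         ionic_strength))
}

# Debye-Huckel A parameter (quadratic fit in Celsius)
davies_a <- function(temperature, constants = default_constants()) {
  d <- constants$davies
  tc <- temperature - 273.15
  d$a0 + d$a1 * tc + d$a2 * tc^2
}

# mole-fraction-style water activity from total solute molality
water_activity <- function(total_molality) {
  max(1 - 0.018015 * total_molality, 0.5)
}
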