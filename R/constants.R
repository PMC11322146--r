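#' Load a versioned set of thermodynamic constants
#'
#' All thermodynamic inputs of the package — gas critical constants and
#' acentric factors for the Peng-Robinson equation of state, Henry-law
#' coefficients, aqueous mass-action constants with their temperature
#' dependence, half-reaction log K values, Davies activity-model
#' coefficients, and standard formation data — live in a versioned
#' structured-text file so that every result is reproducible per constants
#' version.
#'
#' @param version Constants-file version string (currently `"1.0"`).
#' @param path Optional explicit path to a constants file; overrides
#'   `version`.
#' @return An object of class `thermo_constants`: a list with elements
#'   `version`, `tref` (reference temperature, K), `R` (gas constant,
#'   J/mol/K), `F` (Faraday constant, A s/mol), `p_atm` (bar), `davies`,
#'   `gases`, `equilibria`, `half_reactions` and `formation`.
#' @examples
#' cst <- thermo_constants()
#' cst$R
#' log_k(cst, "carbonic_1", 309.15)
#' @export
thermo_constants <- function(version = "1.0", path = NULL) {
  if (is.null(path)) {
    fname <- paste0("thermo_constants_v", sub("\\.0$", "", version), ".yaml")
    path <- system.file("extdata", fname, package = "aquiferh2")
    if (path == "") {
      stop("no constants file for version '", version, "'", call. = FALSE)
    }
  }
  raw <- yaml::read_yaml(path)
  stopifnot(is.character(raw$version))
  structure(
    list(
      version = raw$version,
      tref = raw$reference_temperature,
      R = raw$gas_constant,
      F = raw$faraday_constant,
      p_atm = raw$atmospheric_pressure,
      davies = raw$davies,
      gases = raw$gases,
      equilibria = raw$equilibria,
      half_reactions = raw$half_reactions,
      formation = raw$formation,
      kij = raw$kij
    ),
    class = "thermo_constants"
  )
}

# cache the default constants so hot loops do not re-read the yaml
the <- new.env(parent = emptyenv())

default_constants <- function() {
  if (is.null(the$constants)) the$constants <- thermo_constants()
  the$constants
}

#' @export
print.thermo_constants <- function(x, ...) {
  cat("<thermo_constants> version", x$version, "\n")
  cat("  gases:", paste(names(x$gases), collapse = ", "), "\n")
  cat("  equilibria:", paste(names(x$equilibria), collapse = ", "), "\n")
  cat("  formation species:", length(x$formation), "\n")
  invisible(x)
}

#' Equilibrium constant of a named aqueous equilibrium
#'
#' Evaluates log10 K at temperature `temperature`.  Entries carry either an
#' analytic expression `logK(T) = a1 + a2*T + a3/T + a4*log10(T)` or a
#' reference-temperature value extrapolated by the van 't Hoff relation from
#' the tabulated reaction enthalpy.
#'
#' @param constants A [thermo_constants()] object.
#' @param name Equilibrium name, e.g. `"carbonic_1"`, `"calcite"`.
#' @param temperature Temperature (K).
#' @return log10 of the equilibrium constant.
#' @export
log_k <- function(constants, name, temperature) {
  eq <- constants$equilibria[[name]]
  if (is.null(eq)) eq <- constants$half_reactions[[name]]
  if (is.null(eq)) {
    stop("no equilibrium '", name, "' in constants file version ",
         constants$version, call. = FALSE)
  }
  if (!is.null(eq$analytic)) {
    a <- eq$analytic
    a$a1 + a$a2 * temperature + a$a3 / temperature + a$a4 * log10(temperature)
  } else {
    vant_hoff(eq$logk, eq$dh, temperature, constants$tref, constants$R)
  }
}

# van 't Hoff extrapolation of a log10 K; dh in J/mol
vant_hoff <- function(logk_ref, dh, temperature, tref, R = 8.314) {
  logk_ref - dh / (R * log(10)) * (1 / temperature - 1 / tref)
}

#' Henry-law coefficient of a gas
#'
#' @inheritParams log_k
#' @param species Gas name: `"CH4"`, `"CO2"`, `"H2"`, `"N2"` or `"H2S"`.
#' @return Henry coefficient in mol/kg/bar, so that the dissolved neutral
#'   molality is `KH * fugacity`.
#' @export
henry_constant <- function(constants, species, temperature) {
  g <- constants$gases[[species]]
  if (is.null(g)) {
    stop("no gas '", species, "' in constants file; add a gases entry with ",
         "kh0/kh_dh for it", call. = FALSE)
  }
  g$kh0 * exp(-g$kh_dh / constants$R * (1 / temperature - 1 / constants$tref))
}

# formation-data lookup; errs naming the missing species
formation_data <- function(constants, species) {
  f <- constants$formation[[species]]
  if (is.null(f)) {
    stop("no standard formation data for species '", species,
         "' in constants file version ", constants$version, call. = FALSE)
  }
  f
}
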