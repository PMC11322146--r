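# Stoichiometric schemes of the four hydrogenotrophic metabolisms.
#
# sulfate reduction : SO4-- + 4 H2 + (1+x) CO2 ->
#                       x H2S + (1-x) HS- + (1+x) HCO3- + (3-x) H2O
# acetogenesis      : CO2 + HCO3- + 4 H2 -> CH3COO- + 3 H2O
# formate production: HCO3- + H2 -> HCOO- + H2O
# methanogenesis    : CO2 + 4 H2 -> CH4 + 2 H2O
#
# where x is the H2S fraction of the sulfide split at the prevailing pH;
# each scheme is combined with the CO2/HCO3- acid-base couple so that the
# H+ turnover is buffered, which is why sulfate reduction carries the
# (1+x) CO2 -> (1+x) HCO3- term.

SCHEME_NAMES <- c("sulfate_reduction", "acetogenesis",
                  "formate_production", "methanogenesis")

# default active windows (days): sulfate reduction runs from H2 injection
# to total consumption of the re-added sulfate; methanogenesis from first
# methanogen activity
DEFAULT_WINDOWS <- list(
  sulfate_reduction = c(9, 21),
  acetogenesis = c(9, 105),
  formate_production = c(9, 105),
  methanogenesis = c(35, 105)
)

# element composition (H, C, O, S) and charge of the scheme species
SPECIES_ELEMENTS <- list(
  "SO4--" = c(H = 0, C = 0, O = 4, S = 1, z = -2),
  "H2(aq)" = c(H = 2, C = 0, O = 0, S = 0, z = 0),
  "CO2(aq)" = c(H = 0, C = 1, O = 2, S = 0, z = 0),
  "H2S(aq)" = c(H = 2, C = 0, O = 0, S = 1, z = 0),
  "HS-" = c(H = 1, C = 0, O = 0, S = 1, z = -1),
  "HCO3-" = c(H = 1, C = 1, O = 3, S = 0, z = -1),
  "H2O(l)" = c(H = 2, C = 0, O = 1, S = 0, z = 0),
  "CH3COO-" = c(H = 3, C = 2, O = 2, S = 0, z = -1),
  "HCOO-" = c(H = 1, C = 1, O = 2, S = 0, z = -1),
  "CH4(aq)" = c(H = 4, C = 1, O = 0, S = 0, z = 0)
)

#' Build a microbial reaction scheme
#'
#' Returns the stoichiometric vector of one of the four hydrogenotrophic
#' metabolisms.  The sulfide coefficients of sulfate reduction are set by
#' the sulfide split at the supplied pH and temperature (or frozen at the
#' canonical 0.93/0.07 with `split`); the other three schemes are
#' pH-independent.  Every scheme balances H, C, O, S and charge exactly.
#'
#' @param name One of `"sulfate_reduction"`, `"acetogenesis"`,
#'   `"formate_production"`, `"methanogenesis"`.
#' @param pH pH at which the sulfide split is evaluated (sulfate reduction
#'   only).
#' @param temperature Temperature (K) for the split.
#' @param split Optional frozen sulfide split, e.g. `c(x_h2s = 0.93,
#'   x_hs = 0.07)`.
#' @param window Active window `c(start_day, end_day)`; defaults to the
#'   study windows.
#' @param constants A [thermo_constants()] object.
#' @return A `reaction_scheme`: stoichiometric coefficients `nu`
#'   (reactants negative), `h2_per_extent`, `ic_per_extent` (net inorganic
#'   carbon consumed per unit extent), `marker` species and sign, and the
#'   active `window`.
#' @examples
#' reaction_scheme("sulfate_reduction", pH = 6.0)
#' reaction_scheme("methanogenesis")
#' @export
reaction_scheme <- function(name, pH = 7, temperature = 298.15,
                            split = NULL, window = NULL,
                            constants = default_constants()) {
  if (!name %in% SCHEME_NAMES) {
    stop("unknown scheme '", name, "'; valid schemes: ",
         paste(SCHEME_NAMES, collapse = ", "), call. = FALSE)
  }
  if (is.null(window)) window <- DEFAULT_WINDOWS[[name]]
  nu <- switch(
    name,
    sulfate_reduction = {
      if (is.null(split)) {
        split <- sulfide_split(pH, temperature, constants = constants)
      }
      x <- split[[1]]
      c("SO4--" = -1, "H2(aq)" = -4, "CO2(aq)" = -(1 + x),
        "H2S(aq)" = x, "HS-" = 1 - x, "HCO3-" = 1 + x, "H2O(l)" = 3 - x)
    },
    acetogenesis = c("CO2(aq)" = -1, "HCO3-" = -1, "H2(aq)" = -4,
                     "CH3COO-" = 1, "H2O(l)" = 3),
    formate_production = c("HCO3-" = -1, "H2(aq)" = -1, "HCOO-" = 1,
                           "H2O(l)" = 1),
    methanogenesis = c("CO2(aq)" = -1, "H2(aq)" = -4, "CH4(aq)" = 1,
                       "H2O(l)" = 2)
  )
  marker <- switch(name,
    sulfate_reduction = "so4", acetogenesis = "acetate",
    formate_production = "formate", methanogenesis = "ic")
  marker_sign <- if (name == "sulfate_reduction" ||
                     name == "methanogenesis") -1 else 1
  obj <- structure(
    list(name = name, nu = nu,
         h2_per_extent = -nu[["H2(aq)"]],
         ic_per_extent = ic_consumed(nu),
         sulfide_per_extent = if (name == "sulfate_reduction") 1 else 0,
         marker = marker, marker_sign = marker_sign,
         window = window),
    class = "reaction_scheme"
  )
  check_scheme_balance(obj)
  obj
}

# net inorganic carbon consumed per unit extent (CO2 + HCO3- reactants
# minus CO2 + HCO3- products)
ic_consumed <- function(nu) {
  ic <- 0
  for (sp in c("CO2(aq)", "HCO3-")) {
    if (sp %in% names(nu)) ic <- ic - nu[[sp]]
  }
  ic
}

check_scheme_balance <- function(scheme, tol = 1e-10) {
  bal <- c(H = 0, C = 0, O = 0, S = 0, z = 0)
  for (sp in names(scheme$nu)) {
    el <- SPECIES_ELEMENTS[[sp]]
    if (is.null(el)) stop("no element data for scheme species ", sp,
                          call. = FALSE)
    bal <- bal + scheme$nu[[sp]] * el
  }
  if (max(abs(bal)) > tol) {
    stop("scheme '", scheme$name, "' does not balance: ",
         paste(names(bal), signif(bal, 3), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.reaction_scheme <- function(x, ...) {
  lhs <- x$nu[x$nu < 0]; rhs <- x$nu[x$nu > 0]
  term <- function(v) paste(paste0(signif(abs(v), 3), " ", names(v)),
                            collapse = " + ")
  cat("<reaction_scheme> ", x$name, "\n  ", term(lhs), " -> ", term(rhs),
      "\n  H2/extent ", x$h2_per_extent, ", inorganic C/extent ",
      x$ic_per_extent, ", window days ", x$window[1], "-", x$window[2],
      "\n", sep = "")
  invisible(x)
}

#' The four study schemes at a common pH
#'
#' @param pH,temperature Conditions for the sulfide split.
#' @param windows Optional named list overriding the default active
#'   windows.
#' @param split Optional frozen sulfide split (see [reaction_scheme()]).
#' @param constants A [thermo_constants()] object.
#' @return Named list of [reaction_scheme()] objects.
#' @export
study_schemes <- function(pH = 6.05, temperature = 309.15, windows = NULL,
                          split = NULL, constants = default_constants()) {
  out <- purrr::map(
    stats::setNames(SCHEME_NAMES, SCHEME_NAMES),
    function(nm) reaction_scheme(
      nm, pH = pH, temperature = temperature, split = split,
      window = windows[[nm]], constants = constants)
  )
  out
}
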