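# broom-style tidiers for the package's result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a speciation result
#'
#' @param x A [speciate()] result.
#' @param ... Unused.
#' @return The per-species tibble (species, charge, molality, gamma,
#'   activity).
#' @export
tidy.speciation <- function(x, ...) x$species

#' @rdname tidy.speciation
#' @return `glance()`: one row with pH, ionic strength, calcite SI,
#'   charge imbalance, DIC and the constants version.
#' @export
glance.speciation <- function(x, ...) {
  tibble::tibble(
    pH = x$pH, ionic_strength = x$ionic_strength,
    si_calcite = x$si_calcite, charge_imbalance = x$charge_imbalance,
    dic = x$dic, temperature = x$temperature,
    constants_version = x$constants_version
  )
}

#' Tidy an extent trajectory
#'
#' @param x A [compute_extents()] result.
#' @param ... Unused.
#' @return The per-interval tibble with extents, H2/inorganic-carbon
#'   consumption and sulfide production.
#' @export
tidy.extent_trajectory <- function(x, ...) x$intervals

#' @rdname tidy.extent_trajectory
#' @return `glance()`: one row per scheme with total extent, H2 consumed,
#'   sulfide produced and propagated sigma.
#' @export
glance.extent_trajectory <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$intervals, .data$scheme),
    extent = sum(.data$extent),
    h2_consumed = sum(.data$h2_consumed),
    ic_consumed = sum(.data$ic_consumed),
    sulfide_produced = sum(.data$sulfide_produced),
    sigma = sqrt(sum(.data$sigma^2)),
    clipped = sum(abs(.data$clipped)),
    .groups = "drop"
  )
}

#' Tidy an in situ reconstruction
#'
#' @param x A [reconstruct_insitu()] result.
#' @param ... Unused.
#' @return One row per reconstructed quantity with value and (when
#'   [propagate_uncertainty()] has run) its standard deviation.
#' @export
tidy.insitu_reconstruction <- function(x, ...) {
  out <- tibble::tibble(
    quantity = c("pH_insitu", "pH_atmospheric", "e_h2", "e_co2_ch4"),
    value = c(x$pH_insitu, x$pH_atmospheric, x$e_h2, x$e_co2_ch4),
    unit = c("", "", "V", "V")
  )
  if (!is.null(x$uncertainty)) {
    out <- dplyr::left_join(
      out, dplyr::select(x$uncertainty, "quantity", "sd"),
      by = "quantity")
  }
  out
}

#' @rdname tidy.insitu_reconstruction
#' @return `glance()`: one row with the headline quantities.
#' @export
glance.insitu_reconstruction <- function(x, ...) {
  tibble::tibble(
    pH_insitu = x$pH_insitu, pH_atmospheric = x$pH_atmospheric,
    e_h2 = x$e_h2, e_co2_ch4 = x$e_co2_ch4,
    charge_offset = x$charge_offset, degraded = x$degraded
  )
}

#' Tidy an H2/CO2 budget
#'
#' @param x An [h2_co2_budget()] result.
#' @param ... Unused.
#' @return The modeled/measured curves tibble.
#' @export
tidy.h2_budget <- function(x, ...) x$curves

#' @rdname tidy.h2_budget
#' @export
glance.h2_budget <- function(x, ...) {
  tibble::tibble(
    h2_injected = max(x$curves$h2_injected),
    h2_consumed_modeled = max(x$curves$h2_consumed),
    main_consumer = x$attribution$scheme[which.max(x$attribution$h2_mol)]
  )
}

#' Tidy reaction thermodynamics
#'
#' @param x A [reaction_thermo()] result.
#' @param ... Unused.
#' @export
tidy.reaction_thermo <- function(x, ...) {
  tibble::tibble(
    term = c("dg_tref", "dh", "dg_t", "K"),
    value = c(x$dg_tref, x$dh, x$dg_t, x$K),
    unit = c("kJ/mol", "kJ/mol", "kJ/mol", "")
  )
}
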