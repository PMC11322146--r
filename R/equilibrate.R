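# Closed-system gas-liquid(-calcite) equilibration of the reactor.
#
# Unknowns are the log gas-phase amounts of the volatile species, the pH,
# and (with calcite active) the calcite transfer; a damped Newton iteration
# with a numerical Jacobian drives the per-species mass balances, the
# charge balance and the calcite saturation index to zero.  Working in log
# coordinates keeps the stiff span of concentrations well-conditioned.

VOLATILES <- c("CH4", "CO2", "H2", "N2", "H2S")
# aqueous total component fed by each volatile
VOL_COMPONENT <- c(CH4 = "ch4", CO2 = "dic", H2 = "h2", N2 = "n2",
                   H2S = "sulfide")

#' Construct a reactor state
#'
#' Couples a [gas_phase()] headspace, an [aqueous_solution()] and an
#' optional calcite pool at a common temperature.
#'
#' @param gas A [gas_phase()].
#' @param solution An [aqueous_solution()].
#' @param calcite_mol Calcite pool (mol); the rock of the studied aquifer is
#'   12 % calcite, so the reactor pool is effectively unlimited.
#' @return A `reactor_state` object.
#' @examples
#' st <- reactor_state(
#'   gas_phase(CH4 = 4.54, CO2 = 4.58e-2, temperature = 309.15,
#'             pressure = 62),
#'   mixed_water(1.85, temperature = 309.15),
#'   calcite_mol = 0.5
#' )
#' @export
reactor_state <- function(gas, solution, calcite_mol = 0) {
  stopifnot(inherits(gas, "gas_phase"), inherits(solution, "aqueous_solution"))
  if (abs(gas$temperature - attr(solution, "temperature")) > 1e-9) {
    stop("gas and solution temperatures differ", call. = FALSE)
  }
  if (calcite_mol < 0) stop("calcite pool must be >= 0", call. = FALSE)
  structure(
    list(gas = gas, solution = solution, calcite_mol = calcite_mol,
         temperature = gas$temperature, pressure = gas$pressure,
         volume = gas$volume, speciation = NULL, diagnostics = NULL),
    class = "reactor_state"
  )
}

#' @export
print.reactor_state <- function(x, ...) {
  cat("<reactor_state> ", format(x$pressure, digits = 4), "bar,",
      format(x$temperature, digits = 5), "K, headspace",
      format(x$volume, digits = 4), "L, calcite",
      format(x$calcite_mol, digits = 4), "mol\n")
  print(x$gas)
  if (!is.null(x$speciation)) {
    cat("  pH", format(x$speciation$pH, digits = 4), "\n")
  }
  invisible(x)
}

# component totals of a reactor state (mol), one entry per volatile plus
# the calcite pool; used for the conservation check
state_inventory <- function(state) {
  kg <- attr(state$solution, "mass_kg")
  tot <- solution_totals(state$solution)
  n <- state$gas$amounts
  gas_amt <- function(sp) if (sp %in% names(n)) n[[sp]] else 0
  c(CH4 = gas_amt("CH4") + tot[["ch4"]] * kg,
    H2 = gas_amt("H2") + tot[["h2"]] * kg,
    N2 = gas_amt("N2"),
    C = gas_amt("CO2") + tot[["dic"]] * kg + state$calcite_mol,
    S = gas_amt("H2S") + tot[["sulfide"]] * kg,
    Ca = tot[["ca"]] * kg + state$calcite_mol)
}

#' Equilibrate a reactor state
#'
#' Partitions the volatile inventories (CH4, CO2, H2, N2, H2S) between the
#' headspace and the water so that every gas fugacity matches its Henry-law
#' dissolved activity, fully speciates the aqueous phase, and — when
#' `calcite = TRUE` — dissolves or precipitates calcite until its
#' saturation index is zero or the pool empties.  Element totals are
#' conserved to the solver tolerance.
#'
#' In `fixed_volume` mode the headspace volume is held and the pressure
#' follows from the equation of state; `fixed_pressure` mode mirrors the
#' experiment's piston, shrinking the headspace as gas dissolves.  If at
#' fixed pressure the whole volatile inventory is subsaturated (bubble
#' pressure below the imposed pressure), the gas phase disappears and a
#' single-phase speciation is returned.
#'
#' @param state A [reactor_state()].
#' @param mode `"fixed_volume"` or `"fixed_pressure"`.
#' @param calcite Allow calcite to react (default TRUE).
#' @param ideal_gas Replace Peng-Robinson fugacities by the ideal-gas law.
#' @param constants A [thermo_constants()] object.
#' @param tol Convergence tolerance on the scaled residuals.
#' @param max_iter Newton iteration cap.
#' @return A new `reactor_state` with equilibrated gas and solution, the
#'   final `speciation` attached, and `diagnostics` (iterations, residual,
#'   element-conservation error).
#' @examples
#' st <- reactor_state(
#'   gas_phase(CH4 = 4.54, CO2 = 4.58e-2, temperature = 309.15,
#'             pressure = 62),
#'   mixed_water(1.85, temperature = 309.15), calcite_mol = 0.5
#' )
#' eq <- equilibrate(st)
#' eq$speciation$pH
#' @export
equilibrate <- function(state, mode = c("fixed_volume", "fixed_pressure"),
                        calcite = TRUE, ideal_gas = FALSE,
                        constants = default_constants(),
                        tol = 1e-11, max_iter = 100) {
  mode <- match.arg(mode)
  stopifnot(inherits(state, "reactor_state"))
  TT <- state$temperature
  kg <- attr(state$solution, "mass_kg")
  offset <- attr(state$solution, "charge_offset")
  inv <- state_inventory(state)
  tot0 <- solution_totals(state$solution)
  kh <- vapply(VOLATILES, function(s) henry_constant(constants, s, TT),
               numeric(1))

  totals <- c(CH4 = inv[["CH4"]], CO2 = inv[["C"]] - state$calcite_mol,
              H2 = inv[["H2"]], N2 = inv[["N2"]], S = inv[["S"]])
  active <- VOLATILES[c(totals[["CH4"]] > 0, totals[["CO2"]] > 0,
                        totals[["H2"]] > 0, totals[["N2"]] > 0,
                        totals[["S"]] > 0)]
  if (length(active) == 0) stop("no volatile inventory to equilibrate",
                                call. = FALSE)
  tot_act <- c(CH4 = totals[["CH4"]], CO2 = totals[["CO2"]],
               H2 = totals[["H2"]], N2 = totals[["N2"]],
               H2S = totals[["S"]])[active]

  if (mode == "fixed_pressure") {
    bub <- bubble_pressure(tot_act, kg, tot0, TT, offset, constants,
                           ideal_gas)
    if (bub < state$pressure) {
      return(single_phase_state(state, tot_act, constants, calcite))
    }
  }

  do_cal <- calcite
  res <- equil_newton(state, mode, active, tot_act, kh, do_cal,
                      ideal_gas, constants, tol, max_iter)
  if (do_cal && (state$calcite_mol - res$xi) < 0) {
    # pool empties: dissolve it all, drop the saturation constraint
    res <- equil_newton(state, mode, active, tot_act, kh, FALSE,
                        ideal_gas, constants, tol, max_iter,
                        xi_fixed = state$calcite_mol)
  }
  assemble_state(state, res, active, constants, mode, ideal_gas)
}

# core Newton iteration; returns gas amounts, pH, xi, speciation pieces
equil_newton <- function(state, mode, active, tot_act, kh, calcite,
                         ideal_gas, constants, tol, max_iter,
                         xi_fixed = 0) {
  TT <- state$temperature
  kg <- attr(state$solution, "mass_kg")
  offset <- attr(state$solution, "charge_offset")
  tot0 <- solution_totals(state$solution)
  V <- state$volume
  P_fix <- state$pressure
  nsp <- length(active)
  track_co2 <- "CO2" %in% active
  track_h2s <- "H2S" %in% active

  residual <- function(x, want_eval = FALSE) {
    n_g <- exp(x[seq_len(nsp)])
    names(n_g) <- active
    pH <- x[nsp + 1]
    xi <- if (calcite) x[nsp + 2] else xi_fixed
    y <- n_g / sum(n_g)
    P <- if (mode == "fixed_volume") {
      if (ideal_gas) sum(n_g) * RGAS_LBAR * TT / V
      else pr_pressure(y, TT, V / sum(n_g), constants)
    } else P_fix
    if (!is.finite(P) || P <= 0) return(rep(1e6, length(x)))
    phi <- if (ideal_gas) stats::setNames(rep(1, nsp), active)
           else pr_fugacity_coefficients(y, TT, P, constants)
    f <- y * P * phi

    if (!all(is.finite(f))) return(rep(1e6, length(x)))
    tot_aq <- tot0
    tot_aq[["ca"]] <- tot0[["ca"]] + xi / kg
    for (sp in intersect(active, c("CH4", "H2"))) {
      tot_aq[[VOL_COMPONENT[[sp]]]] <- kh[[sp]] * f[[sp]]
    }
    co2_aq <- if (track_co2) kh[["CO2"]] * f[["CO2"]] else 0
    if (track_h2s) tot_aq[["sulfide"]] <- 0   # re-derived below from f
    ev <- tryCatch(
      aq_eval(pH, tot_aq, TT, constants, ion_pairs = TRUE,
              co2_aq = co2_aq),
      error = function(e) NULL)
    if (is.null(ev)) return(rep(1e6, length(x)))
    if (track_h2s) {
      mH2S <- kh[["H2S"]] * f[["H2S"]]
      rs <- 10^log_k(constants, "h2s_1", TT) /
        (10^(-pH) * ev$gamma[["HS-"]])
      mHS <- mH2S * rs
    } else {
      mH2S <- 0; mHS <- 0
    }

    r <- numeric(length(x))
    for (i in seq_len(nsp)) {
      sp <- active[i]
      diss <- switch(sp,
        CO2 = ev$dic * kg - xi,
        H2S = (mH2S + mHS) * kg,
        kh[[sp]] * f[[sp]] * kg)
      r[i] <- (n_g[[sp]] + diss - tot_act[[sp]]) / tot_act[[sp]]
    }
    imb <- ev$imbalance - mHS - offset   # HS- re-derived from the gas coupling
    qscale <- max(sum(abs(ev$charge) * ev$molality), 1e-5)
    r[nsp + 1] <- imb / qscale
    if (calcite) r[nsp + 2] <- ev$si_calcite
    if (want_eval) {
      list(r = r, ev = ev, n_g = n_g, P = P, phi = phi, f = f, pH = pH,
           xi = xi, mH2S = mH2S, mHS = mHS)
    } else r
  }

  # initial guess: current gas amounts (or most of the inventory), pH 7
  n0 <- vapply(active, function(sp) {
    cur <- state$gas$amounts
    v <- if (sp %in% names(cur)) cur[[sp]] else 0
    max(v, 0.5 * tot_act[[sp]], 1e-12)
  }, numeric(1))
  pH0 <- if (!is.null(state$speciation)) state$speciation$pH else 7
  x <- c(log(n0), pH0, if (calcite) 0)

  converged <- FALSE
  r <- residual(x)
  for (it in seq_len(max_iter)) {
    if (max(abs(r)) < tol) { converged <- TRUE; break }
    J <- matrix(0, length(x), length(x))
    for (j in seq_along(x)) {
      h <- 1e-7 * max(1, abs(x[j]))
      xp <- x; xp[j] <- x[j] + h
      J[, j] <- (residual(xp) - r) / h
    }
    step <- tryCatch(solve(J, -r), error = function(e) NULL)
    if (is.null(step)) {
      stop("equilibrate: singular Jacobian at iteration ", it, call. = FALSE)
    }
    step <- pmax(pmin(step, 1), -1)           # damping for the stiff span
    # backtracking line search
    ok <- FALSE
    for (lam in c(1, 0.5, 0.25, 0.1)) {
      xn <- x + lam * step
      rn <- residual(xn)
      if (all(is.finite(rn)) && max(abs(rn)) < max(abs(r)) * (1 - 1e-4) ||
          max(abs(rn)) < tol) {
        x <- xn; r <- rn; ok <- TRUE; break
      }
    }
    if (!ok) { x <- x + 0.05 * step; r <- residual(x) }
  }
  if (!converged && max(abs(r)) > 1e-8) {
    stop("equilibrate failed to converge after ", max_iter,
         " iterations; residuals: ",
         paste(signif(r, 3), collapse = ", "), call. = FALSE)
  }
  out <- residual(x, want_eval = TRUE)
  out$iterations <- it
  out$residual <- max(abs(out$r))
  out
}

# build the returned reactor_state from a converged Newton result
assemble_state <- function(state, res, active, constants, mode, ideal_gas) {
  TT <- state$temperature
  kg <- attr(state$solution, "mass_kg")
  m <- res$ev$molality
  sol <- solution_update(
    state$solution,
    dic = res$ev$dic,
    sulfide = res$mH2S + res$mHS,
    ca = m[["Ca++"]] + m[["CaHCO3+"]] + m[["CaSO4(aq)"]],
    h2 = if ("H2" %in% active) m[["H2(aq)"]] else 0,
    ch4 = if ("CH4" %in% active) m[["CH4(aq)"]] else 0
  )
  gas <- do.call(gas_phase, c(
    as.list(res$n_g),
    list(temperature = TT,
         pressure = if (mode == "fixed_pressure") state$pressure else res$P,
         ideal = ideal_gas, constants = constants)
  ))
  new <- reactor_state(gas, sol, calcite_mol = state$calcite_mol - res$xi)
  spc <- speciate(sol, constants, pH = res$pH)
  new$speciation <- spc
  inv0 <- state_inventory(state)
  inv1 <- state_inventory(new)
  new$diagnostics <- list(
    iterations = res$iterations, residual = res$residual,
    conservation = max(abs(inv1 - inv0) / pmax(abs(inv0), 1e-12)),
    calcite_transfer = res$xi
  )
  new
}

# bubble pressure of the fully dissolved inventory: sum of the partial
# pressures each dissolved volatile would demand
bubble_pressure <- function(tot_act, kg, tot0, TT, offset, constants,
                            ideal_gas) {
  tot_aq <- tot0
  for (sp in names(tot_act)) {
    cmp <- VOL_COMPONENT[[sp]]
    tot_aq[[cmp]] <- tot_act[[sp]] / kg
  }
  sol_pH <- tryCatch({
    fn <- function(p) aq_eval(p, tot_aq, TT, constants)$imbalance - offset
    stats::uniroot(fn, c(0, 14), tol = 1e-12)$root
  }, error = function(e) 7)
  ev <- aq_eval(sol_pH, tot_aq, TT, constants)
  n2_aq <- if ("n2" %in% names(tot_aq)) tot_aq[["n2"]] else 0
  f <- c(CH4 = if (tot_aq[["ch4"]] > 0)
           tot_aq[["ch4"]] / henry_constant(constants, "CH4", TT) else 0,
         CO2 = ev$molality[["CO2(aq)"]] /
           henry_constant(constants, "CO2", TT),
         H2 = if (tot_aq[["h2"]] > 0)
           tot_aq[["h2"]] / henry_constant(constants, "H2", TT) else 0,
         N2 = if (n2_aq > 0)
           n2_aq / henry_constant(constants, "N2", TT) else 0,
         H2S = ev$molality[["H2S(aq)"]] /
           henry_constant(constants, "H2S", TT))
  f <- f[f > 0]
  if (length(f) == 0) return(0)
  if (ideal_gas) return(sum(f))
  y <- f / sum(f)
  phi <- pr_fugacity_coefficients(y, TT, max(sum(f), 1e-6), constants)
  sum(f / phi[names(f)])
}

# all gas dissolves: return a gas-free state with a closed speciation
single_phase_state <- function(state, tot_act, constants, calcite) {
  TT <- state$temperature
  kg <- attr(state$solution, "mass_kg")
  upd <- list()
  for (sp in setdiff(names(tot_act), "N2")) {
    upd[[VOL_COMPONENT[[sp]]]] <- tot_act[[sp]] / kg
  }
  sol <- do.call(solution_update, c(list(state$solution), upd))
  spc <- speciate(sol, constants)
  if (calcite && state$calcite_mol > 0 && spc$si_calcite < 0) {
    warning("single-phase state is calcite-undersaturated; ",
            "calcite kinetics not applied in gas-free mode")
  }
  new <- reactor_state(gas_zero_placeholder(state$gas, TT, state$pressure),
                       sol,
                       calcite_mol = state$calcite_mol)
  new$speciation <- spc
  new$diagnostics <- list(iterations = 0, residual = 0,
                          conservation = 0, calcite_transfer = 0,
                          single_phase = TRUE)
  new
}

gas_zero_placeholder <- function(gas, temperature, pressure) {
  structure(
    list(amounts = gas$amounts * 0, fractions = gas$fractions * 0,
         temperature = temperature, pressure = pressure, volume = 0,
         molar_volume = NA_real_, phi = gas$phi * NA,
         fugacities = gas$fugacities * 0, ideal = gas$ideal),
    class = "gas_phase"
  )
}

#' Move the reactor piston
#'
#' Headspace-volume changes are modeled as an instantaneous volume edit at
#' constant gas content followed by re-equilibration.
#'
#' @param state A [reactor_state()].
#' @param new_volume New headspace volume (L).
#' @return The state with the edited headspace (not yet re-equilibrated).
#' @export
set_headspace_volume <- function(state, new_volume) {
  stopifnot(new_volume > 0)
  g <- state$gas
  gas <- do.call(gas_phase, c(as.list(g$amounts),
                              list(temperature = g$temperature,
                                   volume = new_volume, ideal = g$ideal)))
  out <- reactor_state(gas, state$solution, state$calcite_mol)
  out$speciation <- state$speciation
  out
}
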