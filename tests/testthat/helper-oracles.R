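# Independent oracles used to pin expected values.  These deliberately
# share no code with the package: the cubic is solved by Cardano's method
# instead of polyroot(), the speciation oracle is a brute-force pH grid
# search, and the Davies/van-'t-Hoff formulas are written out afresh.

# --- Peng-Robinson oracle ------------------------------------------------

oracle_pr_params <- list(
  CH4 = c(tc = 190.56, pc = 45.99, w = 0.0115),
  CO2 = c(tc = 304.13, pc = 73.77, w = 0.2239),
  H2  = c(tc = 33.19,  pc = 13.13, w = -0.216),
  N2  = c(tc = 126.20, pc = 33.98, w = 0.0372),
  H2S = c(tc = 373.10, pc = 89.63, w = 0.1005)
)

# real roots of z^3 + p2 z^2 + p1 z + p0 by Cardano / trigonometric method
oracle_cubic_roots <- function(p2, p1, p0) {
  q <- (3 * p1 - p2^2) / 9
  r <- (9 * p2 * p1 - 27 * p0 - 2 * p2^3) / 54
  d <- q^3 + r^2
  if (d > 0) {
    s <- sign(r + sqrt(d)) * abs(r + sqrt(d))^(1 / 3)
    t <- sign(r - sqrt(d)) * abs(r - sqrt(d))^(1 / 3)
    roots <- s + t - p2 / 3
  } else {
    theta <- acos(r / sqrt(-q^3))
    roots <- 2 * sqrt(-q) * cos(theta / 3 + c(0, 2, 4) * pi / 3) - p2 / 3
  }
  sort(roots)
}

oracle_pr <- function(y, temperature, pressure) {
  Rb <- 0.0831446
  sps <- names(y)
  a <- b <- numeric(length(sps))
  for (i in seq_along(sps)) {
    p <- oracle_pr_params[[sps[i]]]
    kap <- 0.37464 + 1.54226 * p[["w"]] - 0.26992 * p[["w"]]^2
    al <- (1 + kap * (1 - sqrt(temperature / p[["tc"]])))^2
    a[i] <- 0.45724 * Rb^2 * p[["tc"]]^2 / p[["pc"]] * al
    b[i] <- 0.07780 * Rb * p[["tc"]] / p[["pc"]]
  }
  amix <- 0
  for (i in seq_along(sps)) for (j in seq_along(sps)) {
    amix <- amix + y[i] * y[j] * sqrt(a[i] * a[j])
  }
  bmix <- sum(y * b)
  A <- amix * pressure / (Rb * temperature)^2
  B <- bmix * pressure / (Rb * temperature)
  roots <- oracle_cubic_roots(-(1 - B), A - 3 * B^2 - 2 * B,
                              -(A * B - B^2 - B^3))
  Z <- max(roots[roots > B])
  lnphi <- vapply(seq_along(sps), function(i) {
    sai <- sum(y * sqrt(a[i] * a))
    b[i] / bmix * (Z - 1) - log(Z - B) -
      A / (2 * sqrt(2) * B) * (2 * sai / amix - b[i] / bmix) *
      log((Z + (1 + sqrt(2)) * B) / (Z + (1 - sqrt(2)) * B))
  }, numeric(1))
  list(Z = Z, Vm = Z * Rb * temperature / pressure,
       phi = stats::setNames(exp(lnphi), sps))
}

# --- speciation grid-search oracle ---------------------------------------

# brute-force pH: minimise |charge imbalance| on a 1e-4 pH grid, no ion
# pairs, Davies activity coefficients iterated against the argmin
oracle_speciation_ph <- function(tot, temperature, n_iter = 25) {
  dav_a <- 0.4913 + 6.106e-4 * (temperature - 273.15) +
    3.65e-6 * (temperature - 273.15)^2
  gam <- function(z, I) {
    s <- sqrt(I)
    10^(-dav_a * z^2 * (s / (1 + s) - 0.3 * I))
  }
  pk1 <- 3404.71 / temperature + 0.032786 * temperature - 14.8435
  pk2 <- 2902.39 / temperature + 0.02379 * temperature - 6.4980
  pkw <- 4470.99 / temperature + 0.017060 * temperature - 6.0875
  grid <- seq(0, 14, by = 1e-4)
  aH <- 10^(-grid)
  getz <- function(nm) if (nm %in% names(tot)) tot[[nm]] else 0
  I <- 1e-3
  for (k in seq_len(n_iter)) {
    g1 <- gam(1, I); g2 <- gam(2, I)
    r1 <- 10^(-pk1) / (aH * g1)
    r2 <- 10^(-pk2) * g1 / (aH * g2)
    mco2 <- getz("dic") / (1 + r1 + r1 * r2)
    mhco3 <- mco2 * r1
    mco3 <- mhco3 * r2
    imb <- aH / g1 + 2 * getz("ca") + 2 * getz("mg") + getz("na") +
      getz("k") + 2 * getz("fe") + 2 * getz("ba") -
      (10^(-pkw) / aH / g1 + mhco3 + 2 * mco3 + getz("cl") +
         2 * getz("so4") + getz("acetate") + getz("formate"))
    i <- which.min(abs(imb))
    pH <- grid[i]
    I_new <- 0.5 * (aH[i] / g1 + 10^(-pkw) / aH[i] / g1 + mhco3[i] +
                      4 * mco3[i] + 4 * getz("ca") + 4 * getz("mg") +
                      getz("na") + getz("k") + getz("cl") +
                      4 * getz("so4") + getz("acetate") + getz("formate") +
                      4 * getz("fe") + 4 * getz("ba"))
    if (abs(I_new - I) < 1e-12) break
    I <- I_new
  }
  pH
}

# --- shared fixtures -----------------------------------------------------

# one short default-like simulation reused across test files (built lazily)
sim_cache <- new.env()
get_short_sim <- function() {
  if (is.null(sim_cache$sim)) {
    sim_cache$sim <- simulate_reactor(
      synthetic_scenario(n_days = 40, rel_noise = 0))
  }
  sim_cache$sim
}

random_small_solution <- function() {
  aqueous_solution(
    temperature = runif(1, 278, 330),
    dic = runif(1, 1e-4, 1e-2),
    ca = runif(1, 0, 4e-3),
    na = runif(1, 0, 4e-3),
    cl = runif(1, 0, 2e-3),
    so4 = runif(1, 0, 1e-3)
  )
}
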