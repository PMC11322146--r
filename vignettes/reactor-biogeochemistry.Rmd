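---
title: "Modeling microbial H2 consumption in a high-pressure aquifer reactor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling microbial H2 consumption in a high-pressure aquifer reactor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquiferh2)
library(dplyr)
```

## The system being modeled

When hydrogen is co-injected with natural gas into a deep-aquifer storage,
autochthonous hydrogenotrophic microorganisms can consume it.  In the
low-salinity aquifer this package describes (0.8 % of seawater salinity,
36 °C, ~60 bar), four metabolisms matter:

* sulfate reduction — `SO4^2- + 4 H2 + 1.93 CO2 -> 0.93 H2S + 0.07 HS- +
  1.93 HCO3- + 2.07 H2O`,
* acetogenesis — `CO2 + HCO3- + 4 H2 -> CH3COO- + 3 H2O`,
* formate production — `HCO3- + H2 -> HCOO- + H2O`,
* methanogenesis — `CO2 + 4 H2 -> CH4 + 2 H2O`.

Each scheme is written combined with the CO2/HCO3- acid-base couple so that
proton turnover is buffered; the sulfide coefficients are the H2S/HS- split
at the prevailing pH (the 0.93/0.07 shown corresponds to the in situ pH of
about 6 evaluated at the reference temperature — see `sulfide_split()`).
Because a batch reactor conserves mass, the extent ξ of each reaction can
be *inverted* from the monitored time series of one marker species per
scheme (sulfate, acetate, formate, and total inorganic carbon,
respectively), and 4ξ (1ξ for formate) is the H2 it consumed.

The package implements this inverse calculation together with the
equilibrium chemistry it leans on: a Peng-Robinson description of the
CH4/CO2/H2/N2/H2S headspace, Henry-law dissolution, a charge-balance
aqueous speciation solver, optional calcite equilibrium, the three-step
reconstruction of in situ pH and Nernst potentials from depressurized
samples, and the thermodynamics of formate production.  A forward
simulator generates synthetic reactor histories with known ground truth so
the whole inverse pipeline is testable without external data.

## Aqueous speciation

`speciate()` distributes dissolved inorganic carbon over
CO2(aq)/HCO3-/CO3-- and total sulfide over H2S(aq)/HS-, treats Na, K, Ca,
Mg, Cl, SO4, Fe, Ba, acetate and formate as conservative ions (acetate and
formate are >94 % dissociated above pH 5.5, so their protonation is
neglected), and closes the system on the charge balance with pH as the
unknown.  Activity coefficients come from the Davies equation — the
standard choice for a water of ionic strength well below 0.1 mol/kg — and
are iterated to self-consistency; the model is cut off at I = 0.5 mol/kg
and refuses to extrapolate beyond it.  The CaHCO3+, MgHCO3+ and CaSO4(aq)
ion pairs are included by default; at the ~5 mmol/kg calcium of the
carbonate-buffered reactor water they bind a few percent of the
bicarbonate, which is not negligible for the formate equilibrium below.
pH is defined as −log10 a(H+) throughout, and pK values are evaluated on
the activity scale.

A deliberate design decision is that the charge imbalance of a *measured*
water is never "fixed" by adjusting an ion: it is carried as a constant
offset (`charge_offset`) through every subsequent equilibration, the way
geochemical reaction codes conserve imbalance across reaction steps.  The
published composition of the raw formation water illustrates why: its
printed ions carry roughly +4 % imbalance, so forcing electroneutrality
shifts the computed pH about half a unit above the field value (8.9 vs
8.3).  The solver is validated against a brute-force grid search instead
(pH grid of 1e-4, agreement to 1e-3 on random waters), and the measured
pH is treated as data, not as a constraint.

Mass-action constants live in a versioned constants file
(`thermo_constants()`): analytic log K(T) expressions for the carbonate
system, water and calcite, and van 't Hoff extrapolations from tabulated
enthalpies for the rest.  Every result object records the constants
version, so a run is reproducible bit for bit per version.

## Gas phase and dissolution

The headspace is modeled with the Peng-Robinson equation of state with van
der Waals mixing rules; binary interaction parameters default to zero and
can be pinned in the constants file.  At these conditions the nonideality
is far from cosmetic: CO2 dilute in CH4 at 60 bar has a fugacity
coefficient of ~0.77, and pure CO2 at 36 °C/60 bar (just above its
critical temperature) ~0.73.  The vapor root (largest real root of the
cubic) is always selected — the reactor headspace never crosses the
two-phase envelope.  Water vapor is neglected in the headspace (its
saturation pressure of ~0.06 bar is three orders below the total
pressure).

Dissolution is Henry's law on the fugacity, `m = KH(T) · f`, with KH
correlations referenced to 25 °C and van 't Hoff temperature corrections.
`equilibrate()` couples the two phases (and optionally a calcite pool)
with a damped Newton iteration on the log gas amounts, the pH, and the
calcite transfer; working in log coordinates keeps the ten-decade span of
concentrations well conditioned.  Fixed-volume mode holds the headspace
and lets pressure follow; fixed-pressure mode mirrors the experiment's
piston.  Element totals are conserved to the solver tolerance (the test
suite asserts 1e-10 relative), equilibration is idempotent, and a
subsaturated inventory at fixed pressure collapses cleanly to a
single-phase (gas-free) state — which is exactly what happens when a
syringe sample is recompressed numerically to 60 bar.

Calcite is the only mineral with reactive feedback (the host rock is 12 %
calcite); iron-sulfide precipitation is represented only as a sulfide sink
in the accounting, because the study observed it mineralogically but
provides no kinetics.

## The in situ characterization protocol

Measuring pH at 60 bar is impractical, so the reactor liquid is sampled
into a gas-tight syringe, depressurized, and analysed at 1 atm; the in
situ state is then reconstructed in three steps
(`reconstruct_insitu()`):

1. total inventories = liquid analysis + released gas, with the released
   amounts from the ideal-gas law at 1 atm and sample temperature (no EOS
   correction is warranted at atmospheric pressure), and the N2 the vial
   was flushed with treated as an inert diluent and renormalized away;
2. the gas-liquid equilibrium *in the syringe* is modeled: the measured
   released-gas composition imposes the retained CO2(aq) through Henry's
   law, which splits the measured DIC into CO2(aq) and HCO3-/CO3--
   without using any electrode reading.  The atmospheric-pressure pH
   falls out as a by-product (and lands in the 6.5–7 range the electrodes
   reported), and the charge imbalance of the analysed water is recorded;
3. the inventories are recompressed to reactor temperature and pressure
   carrying that imbalance unchanged, and speciated.  Gas solubilization
   acidifies: the reconstructed in situ pH (≈6.1 on the day-28 sample) is
   about half a unit below the atmospheric-pressure value, and two units
   below the raw formation water.

Because slow redox couples (C, N, S) are never equilibrated, each couple
retains its own Nernst potential; `nernst_potential()` evaluates the
H+/H2 (2-electron) and CO2/CH4 (8-electron) couples from the speciated
activities.  Their difference on every study fixture directly exhibits
the redox disequilibrium of the water.  The half-reaction log K values
are data in the constants file, derived from the pinned formation-energy
set; published databases disagree on these constants at the tens-of-mV
level, so the package asserts the couples' ordering, sign and spread
rather than absolute millivolt values.

Uncertainty is propagated by Monte Carlo (`propagate_uncertainty()`,
default 2000 draws, fixed seed, caller's RNG state preserved) rather than
linearization, because the speciation is strongly nonlinear in DIC near
pH 6.  With the instrument precisions (±5 % on gas volume, composition,
anions and DIC; ±0.2 K on temperatures) the day-28 pH spread is ≈0.05,
consistent in order of magnitude with the ±0.1 the study quotes.

One measured input needed interpretation: the day-28 bicarbonate plateau
is printed as 7.1e-2 mol/kg, but its own ±5 % uncertainty (3.6e-4) and
the neighbouring values (6.6e-3 on day 21) identify the exponent as a
typo; the fixtures use 7.1e-3.  The syringe temperature is not reported
and is pinned at 293.15 K (laboratory ambient); moving it to 298 K shifts
the reconstructed pH by under 0.07.  The released-gas volume and
composition for day 28 were likewise not published;
`ugs_day28_sample()` derives them self-consistently from the printed
headspace composition and liquid DIC by forward-flashing
(`depressurize_sample()`) and solving for the one unknown, the sample's
bicarbonate content.

## Extent inversion and the H2 budget

`compute_extents()` turns the monitored series into per-interval extents.
For a marker species, the event-corrected mole change over an interval is

```
dn = m(t2) c(t2) − m(t1) c(t1) + withdrawn − added
```

with water masses from the `mass_ledger()`, withdrawals removing solute
at the prevailing (interpolated) molality, and additions taken at the
source-water molality.  The sampling convention is explicit: on a
measurement day, additions precede the measurement and the sampling
withdrawal follows it.  Extents are clipped at zero (all four metabolisms
are irreversible sinks here) with the clipped mass reported, and an
interval only counts when its closing measurement lies inside the
scheme's active window.  An interval's extent is attributed to its
closing day, which reproduces the between-measuring-points accounting of
the study: with sulfate monitored through day 15 and acetate next
measured on day 21, sulfate reduction is the sole attributed H2 consumer
before sulfate exhaustion.

Methanogenesis has no unique aqueous marker; its extent is the total
inorganic carbon change (headspace CO2 plus the dissolved carbonate
system), corrected for calcite dissolution via the measured calcium
change (calcite is the only calcium source, so ΔCa counts the carbon it
released) and for the inorganic carbon consumed by the other three
schemes.  Because the laboratory DIC is an atmospheric-pressure analysis,
the in situ CO2(aq) is reconstructed from the gas series through the
fugacity/Henry chain (`dissolved_co2 = "reconstruct"`); the forward
simulator records in situ totals directly and uses
`dissolved_co2 = "series"`.

Two bookkeeping parameters are not published and are exposed as
configuration with defaults: the routine sampling withdrawal mass
(0.02 kg per sampling day) and the sulfate-reduction window, which is run
to day 21 so that the sulfate re-added with the day-17 water — consumed
before the next analysis — is counted, as the study's own sulfide total
implies.  Doubling the withdrawal mass moves the cumulative
sulfate-reduction extent by about 1 %, well inside the reported ±50 %
sulfide band.

`h2_co2_budget()` integrates extents into modeled H2(t) and total-carbon
curves and attributes consumption per metabolism; attribution is additive
exactly.  On the study data the modeled consumption exceeds the measured
total-H2 decrease, as expected when fermenters produce some H2 that the
scheme set does not source.

## Formate thermodynamics

Formate production has a small equilibrium constant, so whether formate
accumulates is a thermodynamic question.  `reaction_thermo()` builds
ΔG°r(298.15 K) = Σ νi ΔG°f,i from formation data pinned in the constants
file (−18.96 kJ/mol for `HCO3- + H2(aq) -> HCOO- + H2O`), corrects it to
reactor temperature with the integrated Gibbs-Helmholtz relation
`ΔG(T)/T = ΔG(Tref)/Tref + ΔH (1/T − 1/Tref)` (ΔH = −15.24 kJ/mol; the
reaction is exothermic, so K falls from 2097 at 25 °C to 1685 at 36 °C),
and forms `K = exp(−ΔG(T)/RT)` — the sign convention that makes a
spontaneous reaction have K > 1.  `formate_equilibrium()` then evaluates
the mass-action law `a(HCOO-) = K a(H2) a(HCO3-) / a(H2O)`; since formate
and bicarbonate carry the same charge, their Davies coefficients cancel
and the equilibrium *molality* is first-order in the H2 activity.

The dissolved-H2 activity itself admits two routes
(`dissolved_h2_activity()`): Henry's law on the H2 partial pressure
(default), or on the Peng-Robinson fugacity.  The default was chosen on
physical grounds: the Henry coefficients are low-pressure correlations
referenced to partial pressure, and the PR fugacity coefficient of dilute
H2 in CH4 with k_ij = 0 (~1.10 at 60 bar) is the least constrained number
in the chain, so the default avoids compounding it into the equilibrium;
the fugacity route is one argument away.  At 2.2 mol% H2 and 60 bar the
equilibrium formate is ≈8 mmol/kg against ≈0.13 mmol/kg at 1 bar — a
sixty-fold pressure enhancement that explains why formate is seen in
high-pressure experiments and not at atmospheric pressure.  The
bicarbonate entering the calculation is the last analysis before the
evaluation day (4.9 mmol/kg on day 9 for the day-14 evaluation):
interpolating across the day-17 water addition would mix two different
waters.

## The synthetic reactor

`synthetic_scenario()`/`simulate_reactor()` provide ground truth for the
inverse pipeline.  The default scenario mirrors the studied experiment:
4.54 mol CH4 + 4.58e-2 mol CO2 at 62 bar and 36 °C over 1.85 kg of the
mixed formation water with reactive calcite; a gas top-up after the
day-7 piston move, a 2.2 mol% H2 injection on day 9, a 0.353 kg water
addition on day 17, and 0.02 kg sampling withdrawals on measurement
days.  Day 0 is recorded as charged, before equilibration, matching how
the experiment's day-0 analyses were taken.  Reactions advance at
zero-order rates inside onset windows with hard substrate caps — the
simplest kinetics whose cumulative extents are unambiguous ground truth
(the study fits no kinetics, so Monod parameters would be invented
detail); the default rates are sized so sulfate is exhausted shortly
after the re-addition and H2 declines by a few hundredths of a mole over
the run, the observed magnitudes.  Measurement noise is multiplicative
Gaussian (5 % default, matching the instruments' relative precision) and
a scenario's seed fully determines its realisation.

The simulator emulates the measured observables and their event
structure, not everything about real data: no fermentative H2 sources,
no biomass dynamics, no iron-sulfide kinetics, no benzene/toluene
partitioning, and noise that is independent across days and species.
Passing the recovery tests therefore shows that the *inversion* is
exact and noise-calibrated, not that the biology is simple.

## Numerical choices and validation scale

Speciation closes mass-action residuals far below 1e-10 in log units and
the charge balance to the uniroot tolerance (1e-13); the two-phase Newton
converges in 5–15 iterations to scaled residuals below 1e-11, with a
backtracking line search and a single re-solve when the calcite pool
empties.  Ion-pair fixed points converge in a handful of iterations at
millimolal concentrations.  The test suite validates against independent
oracles built first: a Cardano-method cubic solver for the EOS, a 1e-4 pH
grid search for speciation (100 random waters), hand-evaluated formulas
for Davies, Gibbs-Helmholtz and Nernst expressions, and
simulator-vs-inversion round trips (8 randomized 30-day scenarios exactly
and under 5 % noise, 8 depressurization round trips, Monte-Carlo
uncertainty at a few hundred draws).  These sizes keep the default suite
under a minute while leaving every assertion at its stated tolerance;
the full-length (105-day) default scenario runs once.

Known limitations: the Davies model restricts validity to low-salinity
waters; the carbonate constants are freshwater analytic expressions, not
seawater ones; no H2O-rich phase or water vapor in the EOS; no kinetic
mineral rates; the half-reaction log K set reproduces the *structure* of
the redox disequilibrium but absolute potentials depend on the chosen
database; and the methanogenesis extent inherits every uncertainty of the
total-carbon bookkeeping, which is why it is the softest number the
inversion produces.
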