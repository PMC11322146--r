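# Thermodynamic constants, version 1.0
# Units: temperatures K, pressures bar, molalities mol/kg water,
# energies kJ/mol unless noted (van 't Hoff enthalpies dh in J/mol).
# log K temperature dependence: either van 't Hoff from {logk, dh} at tref,
# or an analytic expression  logK(T) = a1 + a2*T + a3/T + a4*log10(T).
version: "1.0"
reference_temperature: 298.15
gas_constant: 8.314          # J/mol/K
faraday_constant: 96485.0    # A s/mol
atmospheric_pressure: 1.01325  # bar

davies:
  # Debye-Huckel A parameter as a quadratic in Celsius temperature
  # (0.5092 at 25 C, 0.5241 at 45 C)
  a0: 0.4913
  a1: 6.106e-4
  a2: 3.65e-6
  linear_term: 0.3
  max_ionic_strength: 0.5

gases:
  # Peng-Robinson critical constants / acentric factors and Henry-law
  # coefficients: kh0 mol/kg/bar at tref, van 't Hoff enthalpy of
  # dissolution dh (J/mol): KH(T) = kh0 * exp(-dh/R * (1/T - 1/tref)).
  CH4: {tc: 190.56, pc: 45.99, omega: 0.0115,  kh0: 1.40e-3, kh_dh: -13300.0}
  CO2: {tc: 304.13, pc: 73.77, omega: 0.2239,  kh0: 3.39e-2, kh_dh: -19983.0}
  H2:  {tc: 33.19,  pc: 13.13, omega: -0.216,  kh0: 7.85e-4, kh_dh: -4184.0}
  N2:  {tc: 126.20, pc: 33.98, omega: 0.0372,  kh0: 6.40e-4, kh_dh: -10800.0}
  H2S: {tc: 373.10, pc: 89.63, omega: 0.1005,  kh0: 1.02e-1, kh_dh: -17500.0}

equilibria:
  # Aqueous mass-action constants.  Charges in species names use +/-.
  carbonic_1:            # CO2(aq) + H2O = H+ + HCO3-
    analytic: {a1: 14.8435, a2: -0.032786, a3: -3404.71, a4: 0.0}
  carbonic_2:            # HCO3- = H+ + CO3--
    analytic: {a1: 6.4980, a2: -0.02379, a3: -2902.39, a4: 0.0}
  water:                 # H2O = H+ + OH-
    analytic: {a1: 6.0875, a2: -0.017060, a3: -4470.99, a4: 0.0}
  h2s_1:                 # H2S(aq) = H+ + HS-
    logk: -6.994
    dh: 22180.0
  calcite:               # CaCO3(s) = Ca++ + CO3--
    analytic: {a1: -171.9065, a2: -0.077993, a3: 2839.319, a4: 71.595}
  ca_hco3:               # Ca++ + HCO3- = CaHCO3+
    logk: 1.106
    dh: 12850.0
  mg_hco3:               # Mg++ + HCO3- = MgHCO3+
    logk: 1.07
    dh: 3310.0
  ca_so4:                # Ca++ + SO4-- = CaSO4(aq)
    logk: 2.30
    dh: 6900.0

half_reactions:
  # Reduction half reactions, log K at tref from the formation data below.
  h_h2:                  # 2 H+ + 2 e- = H2(aq)
    logk: -3.0836
    dh: -4200.0
    electrons: 2
  co2_ch4:               # CO2(aq) + 8 H+ + 8 e- = CH4(aq) + 2 H2O
    logk: 21.480
    dh: -246900.0
    electrons: 8

formation:
  # Standard Gibbs energies / enthalpies of formation at 298.15 K, 1 bar
  # (NBS tables), kJ/mol.
  "HCOO-":     {gf: -351.0,   hf: -425.6,   charge: -1}
  "CH3COO-":   {gf: -369.31,  hf: -486.01,  charge: -1}
  "HCO3-":     {gf: -586.77,  hf: -691.99,  charge: -1}
  "CO3--":     {gf: -527.81,  hf: -677.14,  charge: -2}
  "CO2(aq)":   {gf: -385.98,  hf: -413.80,  charge: 0}
  "H2(aq)":    {gf: 17.6,     hf: -4.2,     charge: 0}
  "CH4(aq)":   {gf: -34.33,   hf: -89.04,   charge: 0}
  "H2O(l)":    {gf: -237.129, hf: -285.83,  charge: 0}
  "H2S(aq)":   {gf: -27.83,   hf: -38.6,    charge: 0}
  "HS-":       {gf: 12.08,    hf: -17.6,    charge: -1}
  "SO4--":     {gf: -744.53,  hf: -909.27,  charge: -2}
  "Ca++":      {gf: -553.58,  hf: -542.83,  charge: 2}
  "H+":        {gf: 0.0,      hf: 0.0,      charge: 1}
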