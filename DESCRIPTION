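Package: aquiferh2
Title: Gas-Liquid-Mineral Equilibrium and Microbial Hydrogen Accounting for
    High-Pressure Aquifer Reactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the biogeochemistry of hydrogen coinjection with natural
    gas in low-salinity deep-aquifer storage, as observed in high-pressure
    batch reactors. Provides a Peng-Robinson description of the CH4/CO2/H2
    headspace, Henry-law gas dissolution, a Davies-equation aqueous
    speciation solver with optional calcite equilibrium, reconstruction of
    in situ pH and Nernst redox potentials from depressurized syringe
    samples, stoichiometric extent-of-reaction accounting of microbial
    hydrogen consumption (sulfate reduction, acetogenesis, formate
    production, methanogenesis), equilibrium formate thermodynamics, and a
    forward reactor simulator with known ground truth for validating the
    inverse calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
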