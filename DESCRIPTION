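Package: mgcorr
Title: Moving-Boundary Simulation of Magnesium Implant Corrosion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates the aqueous corrosion of a magnesium (alloy) pellet
    through its biphasic corrosion-product layers, Mg -> Mg(OH)2 -> MgCO3,
    as a one-dimensional advection-diffusion system with multiple moving
    interfaces. The porous hydroxide and carbonate layers carry distinct
    solid- and fluid-phase velocities obtained in closed form from mass
    conservation; water and carbon dioxide transport is solved by a
    front-fixing (Landau) transformation and the method of lines with stiff
    integration and event-detected phase transitions. Includes the analytic
    outer-radius and final-size relations, instantaneous- and finite-rate
    surface reaction cases, Cartesian, cylindrical and spherical geometries,
    parameter sweeps with power-law scaling fits, advection-mode
    comparisons, figure presets, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
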