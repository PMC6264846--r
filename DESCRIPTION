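Package: diazosim
Title: Steady-State Metabolic Model of a Heterotrophic Diazotroph in
    Continuous Culture
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained flux-balance simulator of a heterotrophic
    nitrogen-fixing bacterium (Azotobacter vinelandii-like) growing in a
    chemostat on sucrose plus ammonium.  Cellular metabolism is represented
    by balanced half-reactions (mass, electron and energy conservation),
    substrate exchange by diffusion into a spherical cell, and nitrogenase
    is protected from oxygen by respiration in excess of energetic demand.
    The mixed use of dinitrogen and ammonium is chosen to maximize the
    standing stock of biomass at a fixed dilution rate.  Provides steady
    state solvers, parameter sweeps, oxygen-dependent carbon-to-nitrogen
    threshold finders, calibration of the two free parameters, plotting
    helpers and a command line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
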