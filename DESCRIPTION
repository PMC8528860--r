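Package: reefdiv
Title: Paleo-Habitat Dynamics and Reef-Fish Diversification Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links Cenozoic tropical-reef habitat dynamics to lineage
    diversification. Computes habitat fragmentation (patch counts) and
    equal-area habitat surface from stacks of gridded 0/1 paleo-habitat
    maps; fits constant-rate, birth-death-shift, and environment-dependent
    birth-death models to time-calibrated ultrametric phylogenies with
    incomplete present-day sampling; selects models by corrected AIC across
    posterior tree distributions; and summarizes net diversification rates
    through time. Ships simulators for reconstructed trees under
    time-varying rates and for synthetic habitat raster stacks with known
    fragmentation trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
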