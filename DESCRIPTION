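Package: baltfate
Title: Multi-Basin Contaminant Fate Simulation with Coupled Hydrodynamics
    and Biogeochemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale multi-basin box model of organic contaminant fate in a
    brackish sea under combined emission, nutrient-load and climate scenarios.
    Couples a two-layer water and salt balance with surface heat exchange and
    degree-day sea ice, a nutrient-phytoplankton-detritus module with dissolved
    and particulate organic carbon, and a dynamic mass balance for a neutral
    organic chemical (three-phase partitioning, two-film air-water exchange
    with ice blocking, hydrolysis and biodegradation, settling, sediment
    exchange and inter-basin advection). Includes a seeded synthetic weather
    generator, scenario transforms for warming climate and nutrient-load
    trajectories, a paired-scenario comparison engine with strict mass-budget
    accounting, and post-processing metrics (decadal means, emission-measure
    effectiveness, winter concentration peaks, ice-day counts). Defaults
    emulate the fate of decamethylcyclopentasiloxane (D5) in Baltic-like
    basins.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
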