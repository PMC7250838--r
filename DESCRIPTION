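Package: hipe
Title: Human-Impacted Phylogenetic Endemism and Conservation Prioritisation
    Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Spatial and species-level phylogenetic diversity metrics for
    conservation prioritisation on gridded occupancy data. Computes
    phylogenetic diversity (PD), residual PD, weighted endemism (WE),
    evolutionary distinctiveness rarity (EDR) and phylogenetic endemism (PE)
    per grid cell, together with human-pressure-weighted extensions: HIPE
    (human-impacted phylogenetic endemism, which apportions each branch's PD
    across its cells in proportion to Human Footprint derived weights), and
    the species-level scores TE (terminal endemism) and HITE (human-impacted
    terminal endemism). Includes Human Footprint block upscaling and pressure
    categorisation, randomization null models for pressure overlap of
    top-ranked cells, extinction-scenario PD-loss calculations with
    stratified random-extinction nulls, a synthetic-data generator for
    ultrametric trees, spatially contiguous ranges and autocorrelated
    pressure surfaces, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    withr,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
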