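Package: coresat
Title: Core and Satellite Subcommunity Stability in a Mixing Reservoir
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the response of core and satellite
    microeukaryotic subcommunities at two water depths to a complete
    reservoir-mixing disturbance. Provides thermocline detection and
    mixing-period labelling from temperature profiles, occupancy-based
    core/satellite taxon partitioning with abundance categories,
    qPCR-scaled absolute abundances, moving-window inverse coefficient of
    variation (1/CV) community stability, Bray-Curtis beta-diversity
    diagnostics (NMDS, ANOSIM, SIMPER, time-lag analysis), thresholded
    Spearman co-occurrence networks with per-sample subnetwork topology,
    a multi-nutrient cycling index, partial least squares path modelling,
    and a synthetic-data generator that emulates the study design so the
    whole pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    igraph,
    jsonlite,
    withr,
    rlang
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
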