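Package: hotspotr
Title: Spatial Immune Hotspot Analysis for Tumor Microenvironments
Version: 0.1.0
Authors@R:
    person("LATTICe", "Analysis Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for quantifying the spatial organization of
    tumor-infiltrating lymphocytes from single-cell coordinate tables.
    Cells are rasterized onto a 50x50 micrometre lattice and local
    enrichment of cancer cells and lymphocytes is assessed with the
    Getis-Ord Gi* statistic, yielding cancer hotspots, peritumoral and
    intratumoral immune hotspots, and three per-slide spatial scores.
    Individual immune hotspots are segmented by 8-connectivity, cleaned
    of annotated lymphoid structures, and profiled by Delaunay cell-cell
    interaction graphs (link fractions, Shannon diversity, subset
    composition, CD8/Treg ratio). Supporting modules provide
    landmark-based affine registration of serial sections, maximally
    selected log-rank survival dichotomization with repeated random-split
    validation, and a synthetic-slide generator producing multi-class
    clustered point patterns with linked survival outcomes for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
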