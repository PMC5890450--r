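Package: pathmapr
Title: Construction, Scoring and Exploration of Process-Description Signalling Maps
Version: 0.1.0
Authors@R:
    person("pathmapr", "developers", email = "pathmapr@example.org", role = c("aut", "cre"))
Description: A toolkit for comprehensive molecular signalling-network maps drawn
    as SBGN-style process-description diagrams. Reads CellDesigner-flavoured
    SBML, represents maps as typed entity/reaction graphs with structured
    four-section annotations, computes literature-based (REF) and
    PPI-proximity (FUNC) confidence scores, decomposes maps into hierarchical
    layers and functional modules with GMT export, generates pruned
    semantic-zoom views rendered as a raster tile pyramid, and overlays omics
    data (map staining, glyphs, barplots, heatmaps) aggregated over sample
    groups and protein families. A deterministic fixture generator produces
    synthetic maps, PPI networks and omics tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    xml2,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
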