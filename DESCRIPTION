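Package: limnopipe
Title: Harmonization, Georeferencing and Multi-Scale Characterization of
    Lake Water-Quality Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable, tested pipeline for building integrated lake
    water-quality databases from heterogeneous site-level sources.
    Harmonizes arbitrary wide or long source tables into a vertical
    (long-format) observation store using a controlled vocabulary and unit
    registry; georeferences sampling sites to a census population of lake
    polygons with an explicit review queue; characterizes every lake at
    multiple spatial extents (political, hydrologic and buffer zones,
    land-cover composition, hydrologic connectivity on stream networks);
    applies a two-tier rule-based QAQC engine with full provenance and
    audit of deletions; and emits versioned, documented horizontal
    flat-file exports. Includes a seeded synthetic-landscape and
    source-dataset generator with a known-truth ledger so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
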