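Package: endemicrisk
Title: Preliminary IUCN Red-List Assessment and EDGE-Based Spatial
    Prioritization for Endemic Floras
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for national-scale, preliminary extinction-risk screening
    of endemic plant taxa from georeferenced occurrence records. Computes the
    IUCN Criterion B range measures (extent of occurrence, area of occupancy,
    number of locations) on an equal-area projection, infers potential
    population reduction under Criterion A from the overlap of occupied cells
    with human-influence land-cover classes, combines both criteria per taxon,
    and validates the binary threatened/not-threatened classification against
    a reference assessment via a confusion matrix. Scores taxa with the
    fair-proportion evolutionary distinctiveness (ED) and EDGE indices on a
    time-calibrated phylogeny, builds 5-km grid surfaces of endemic,
    threatened and CR richness and mean EDGE, extracts top-1% (L1) hotspot
    cells, and measures their overlap with a protected-area network. A seeded
    synthetic-data generator produces occurrences with designed categories,
    land cover, a phylogeny and protected areas, so the whole pipeline runs
    end-to-end without external downloads. These are preliminary screening
    assessments, not full Red List assessments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    caret,
    geosphere,
    phangorn,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
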