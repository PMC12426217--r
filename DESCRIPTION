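Package: ncpscape
Title: Spatiotemporal Supply-Demand Assessment of Nature's Contributions to People
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the supply of and societal demand for six
    Nature's Contributions to People (pollination, habitat preservation,
    recreation, food, water regulation, climate regulation) on multi-timestep
    categorical landscape rasters, combine them into bounded budget and ratio
    indices per municipality, extract temporal trend coefficients by linear
    regression over timesteps, and group municipalities into spatiotemporal
    archetypes by hierarchical clustering. Includes a seeded synthetic-landscape
    generator (Voronoi municipalities, Markov land-use change, urbanization and
    population-growth gradients, planted archetype structure) so the full
    pipeline runs end-to-end without external data, plus plain-text raster,
    GeoJSON, CSV and YAML readers and writers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    cluster,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
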