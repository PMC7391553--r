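Package: reefrules
Title: Benthic Habitat Typology and Classification Rules for Reef Monitoring Stations
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds a regionally scalable benthic habitat typology from
    station-level habitat attributes recorded by rotating underwater video
    (percent covers of substrate and biota, topography, complexity, depth):
    ordination and hierarchical clustering of coastal stations, supervised
    consolidation and projection of new stations with random-forest
    classifiers, and characterization of each habitat by attribute means.
    Within-habitat heterogeneity is described by top-K class-association
    rules mined under a confidence floor and an antecedent-length cap, and a
    packaged set of 26 expert-selected classification rules predicts habitat
    for new stations with known confidence. Includes fish-community metrics
    by habitat (densities, species richness, family frequencies) and a
    synthetic-station generator with five habitat archetypes so that every
    stage can be exercised without survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    boot,
    randomForest,
    stats,
    utils
Suggests:
    jsonlite,
    MASS,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
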