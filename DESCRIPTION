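Package: habspec
Title: Habitat Specialization Analysis for Soil Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tests whether soil microbial taxa are habitat specialists across
    plant community types sampled on a quadrat lattice. Implements the
    torus-translation habitat-association test (exhaustive translation null
    over four lattice images), weighted bipartite community-microbe network
    modularity (Barber's Q) with a greedy module search, three-way variation
    partitioning of community composition by redundancy analysis with adjusted
    R-squared, and supporting community statistics (Bray-Curtis dissimilarity,
    NMDS, PERMANOVA, habitat-centroid fits, exact species-accumulation
    curves). Includes OTU-table filtering and species-group utilities, a
    synthetic community generator with planted habitat specialists for
    validation, and a pipeline driver producing machine-readable reports.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
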