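Package: howlernet
Title: Individual-Based Primate-Plant Interaction Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing individual-based consumer-resource
    networks from focal-animal feeding observations, motivated by howler monkey
    (Alouatta pigra) diets in continuous and fragmented rain forest. Constructs
    individual x plant incidence matrices from feeding records, computes NODF
    nestedness with probabilistic (Null Model II) Monte-Carlo significance tests,
    network attributes (connectance, links per species, Shannon interaction
    diversity, and the network-level specialization index H2'), categorical
    core-periphery classification by simulated annealing with multi-run occurrence
    percentages, and the accompanying community-side statistics (importance value
    index from forest transects, Jaccard similarity, permutation Mantel tests,
    transformed t-tests, nested ANOVA of feeding-time fractions). Includes a
    synthetic-data generator emulating age/sex-structured foraging data for
    power analysis and testing, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
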