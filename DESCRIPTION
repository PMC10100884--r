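Package: planktonAssembly
Title: Community Assembly Analysis for Plankton Metabarcoding Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing community assembly of phytoplankton and
    microzooplankton from amplicon sequence variant (ASV) tables: input
    validation, singleton filtering and rarefaction; alpha diversity,
    Bray-Curtis ordination and PERMANOVA; distance-decay of similarity
    against geographic and environmental distance; variation partitioning
    between environmental and spatial (dbMEM/PCNM) predictors; Sloan's
    neutral community model with immigration-rate estimation and
    above/neutral/below partitioning of taxa; Levins' niche breadth and a
    pairwise shared-sequence dispersal proxy. Includes seeded simulators of
    neutral (Dirichlet-multinomial) and niche-structured communities so the
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
    ape,
    geosphere,
    picante
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
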