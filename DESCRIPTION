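Package: crcstage
Title: Tumor Microbiome Analysis of Colorectal Cancer Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of 16S ASV tables from benign polyps and the four TNM
    stages of colorectal cancer: post-denoising filtering and rarefaction,
    community ecology (Shannon diversity, Bray-Curtis perMANOVA, canonical
    analysis of principal coordinates, average variation degree, UpSet
    intersection counts, specificity-occupancy specialists, differential
    abundance), co-occurrence-network driver-taxon detection via
    neighbour-shift scores with betweenness change, and a two-stage
    age-deconfounded random-forest model diagnosing benign polyps and each
    cancer stage. Includes a synthetic-cohort generator with planted ground
    truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    MASS,
    ranger,
    stats,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
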