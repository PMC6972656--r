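Package: mosaicscreen
Title: Screening for Mosaically Expressed Marker Genes of Neuronal Sub-Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Implements a prioritisation pipeline for discovering molecular
    markers of neuronal sub-groups from cell-type-specific polysome
    immunoprecipitation (RiboTag) RNA-seq profiles and quantified in situ
    hybridisation atlases. Provides a simplified negative-binomial Wald test
    for differential enrichment between immunoprecipitated cell populations
    with Benjamini-Hochberg correction, gene-ontology category restriction,
    regional expression-density and expression-intensity quantification from
    voxel grids, reference-gene-normalised population-fraction estimation
    with a mosaicism window, curated pattern, cre-driver and literature
    exclusion filters maintained as a nested funnel ledger, and
    immunolabelling co-localisation summaries with per-animal percentages.
    A synthetic-data generator with planted ground truth emulates every
    input so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    withr
Config/testthat/edition: 3
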