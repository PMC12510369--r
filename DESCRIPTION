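Package: ghmine
Title: Glycoside Hydrolase Candidate Mining from Enrichment Metaproteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering carbohydrate-active enzyme candidates from
    microbial enrichment cultures analysed by whole-metagenome sequencing and
    fractionated metaproteomics. Reads open-reading-frame protein databases,
    InterProScan-style functional annotations, DIAMOND-style alignment tables
    and spectral-count identification tables; assigns consensus taxonomic
    lineages by bitscore-weighted voting; screens annotations for glycoside
    hydrolase keywords while retaining unannotated genes; intersects candidates
    with expression and localization evidence (secretome versus cell pellet)
    including a cell-lysis quality control; and ranks candidates by spectral
    count into a reporting table. Two self-contained computations accompany the
    pipeline: an elemental and charge balance solver for aerobic growth
    stoichiometry with ammonium as nitrogen source, and a bond-context
    simulator of pullulan depolymerization by pullulanases and pullulan
    hydrolases. A synthetic-data module generates complete ground-truth
    labelled inputs so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
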