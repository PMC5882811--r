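Package: ctlomics
Title: Multi-Omic Inference of Cytotoxic T Lymphocyte Infiltration Drivers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline linking tumor cytotoxic T lymphocyte (CTL)
    infiltration to neoantigen load in mutation-driven cancers and to
    phospho-ATM/cytokine signaling in copy-number-driven cancers. Provides
    proteomic CTL-high/low calling with per-run iTRAQ missing-value handling,
    an elastic-net RNA-seq CTL score, subsampling plus grid-search gene
    signature derivation, preranked gene set enrichment with leading-edge
    extraction, permutation-based transcription-factor enrichment in protein
    interaction neighborhoods, balanced-subsampling correlation-loss testing,
    and pan-cancer stratified correlation summaries. A synthetic multi-omic
    cohort generator with full ground truth makes every stage testable at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    fgsea,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
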