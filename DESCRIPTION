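Package: tfdistill
Title: Distilling High-Confidence Transcription Factor Interactomes from
    Spectral-Count Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning BioID proximity-labeling and AP-MS
    affinity-purification spectral-count data into high-confidence
    transcription-factor protein-protein interactomes. Implements the
    confidence cascade (SAINT-score threshold followed by method-specific
    CRAPome contaminant-frequency rules), replicate quality control via
    Pearson correlation, interactome network summaries (method overlap,
    known/novel fractions, prey degree, bait-bait edges, NFI partition,
    complex-subunit coverage), bait-by-prey and prey-prey correlation
    clustering with driving-bait attribution, hypergeometric gene-set
    enrichment against a custom background, and a negative-binomial
    synthetic-data generator with planted interactions for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
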