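Package: scopebac
Title: Carrier-Proteome Single-Bacterium Proteomics Analysis and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-bacterium SCoPE-MS experiments using
    TMT-10plex multiplexing with carrier-proteome channels. Provides a synthetic
    data generator emulating the study design (carrier, single-cell, double-cell
    and empty channels with incomplete labeling, stochastic detection and
    isobaric ratio compression), PSM table input/output including a minimal
    mzTab subset, three-layer peptide-spectrum-match validation (dual-validator
    FDR, bulk-abundance-rank and channel-occupancy cutoffs), reporter-ion
    protein quantification with channel-class comparison, and bulk-proteome
    extraction-method summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml,
    digest,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
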