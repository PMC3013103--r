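Package: psmval
Title: Machine-Learning Validation of Peptide-Spectrum Matches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validates Sequest-style peptide-spectrum matches (PSMs) with an
    interpretable machine-learning protocol: in-silico tryptic digestion of a
    protein database defines the observable-peptide universe; probabilistic
    features (Protein Hit Count, Potential Coverage Ratio, PTM percentage,
    spectral-quality statistics) augment the search-engine scores; an
    Alternating Decision Tree classifier produces additive margin scores that
    are logistically calibrated into PSM probabilities and aggregated into
    protein presence probabilities. Includes ROC/AUC and precision-recall
    evaluation with careful tie handling, readers for FASTA, MGF and a
    documented PSM table dialect, and a synthetic search-result simulator so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
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
    optparse,
    pROC,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
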