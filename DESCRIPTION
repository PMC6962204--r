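Package: fucotyper
Title: Classify Core and Outer Fucosylation of N-Glycopeptides from
    Tandem Mass Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies identified N-glycopeptides into four fucosylation
    types (none, core, outer, dual) from CID MS/MS spectra. Extracts the
    relative intensities of 14 diagnostic B/Y fragment ions per
    glycopeptide-spectrum match, trains two probabilistic four-class model
    families (a fully connected neural network and a linear support vector
    machine) over their hyperparameter grids, and filters classifications
    with a decoy-based probability score (Pscore) at a target false
    discovery rate, selecting models by the Euclidean length of accuracy
    and target-decoy AUC. Includes a seeded synthetic-spectrum generator
    and a rule-based oracle so the whole pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
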