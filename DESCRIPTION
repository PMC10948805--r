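Package: aquacurate
Title: Curation and Quality Analytics for Thermodynamic Aqueous Solubility Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for rule-based curation of raw aqueous
    solubility records: a decision tree over experimental metadata
    (buffer/cosolvent, final pH, temperature, substance composition,
    chemical stability, below-LOQ entries, suspicious origins), replicate
    aggregation via the inter-laboratory standard deviation with a
    median-or-discard rule, closed-form solubility baselines (general
    solubility equation, Henderson-Hasselbalch, Johnson ansatz),
    atom/bond sequence fragment descriptors with additive atom
    contributions, error and quality analytics (regression error
    characteristic curves, per-compound median absolute error, stratified
    breakdowns), and an isolation-forest applicability domain with a
    contamination sweep. A synthetic record generator with known ground
    truth exercises every stage without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    stats,
    ggplot2,
    generics,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
SystemRequirements: python3 with the RDKit package on the PATH (used for
    SMILES canonicalization, InChIKey generation and molecular graphs).
Config/testthat/edition: 3
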