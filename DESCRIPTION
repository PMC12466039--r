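Package: pkcascade
Title: Two-Stage Prediction of Human Intravenous Pharmacokinetics from
    Chemical Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts human intravenous pharmacokinetic parameters
    (steady-state volume of distribution, clearance, half-life, fraction
    unbound in plasma and mean residence time) from chemical structure
    with a two-stage cascade: Random Forest models first predict rat, dog
    and monkey pharmacokinetic endpoints from Morgan fingerprints and
    physicochemical descriptors, and those predictions are then injected
    as features into the human-endpoint models. Includes the full data
    curation protocol (SMILES standardization with pH 7.4 protonation,
    duplicate merging, molecular-weight filtering, decadic log
    transforms), repeated nested cross-validation with grid-search model
    selection, fold-error evaluation metrics, a Tanimoto-similarity
    applicability domain with kernel-ridge fold-error estimation,
    chemical-space diagnostics, and a seeded synthetic-data generator.
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
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python'
    on the PATH (configurable via option 'pkcascade.python')
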