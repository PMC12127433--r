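Package: bmcscreen
Title: Benchmark-Concentration Statistics for In Vitro Developmental
    Neurotoxicity Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics for concentration-response screening assays built on
    neural progenitor cell (neurosphere) cultures: normalization of plate-level
    fluorescence data to solvent controls, benchmark-response (BMR) derivation
    from historical control variability, multi-model concentration-response
    fitting over a 13-family catalog with small-sample AIC selection and
    bootstrap confidence bands, benchmark-concentration (BMC/BMCL/BMCU)
    estimation with cytotoxicity gating, Dunnett-Tamhane step-down hit
    classification, most-sensitive-endpoint and sex/species concordance
    analysis, physiological-relevance flagging against cord-blood ligand
    levels, differentially-expressed-gene filtering with gene-set
    overrepresentation, and a synthetic-assay generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
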