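Package: pathopred
Title: Structure-Aware Pathogenicity Classification of Missense Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating structure-aware missense
    variant pathogenicity classifiers on hereditary-cancer gene panels.
    Reads and harmonizes ClinVar-style variant tables, computes per-residue
    structural features (pLDDT, Shrake-Rupley solvent accessible surface
    area and its residue-normalized form) from AlphaFold2-style predicted
    structures, derives sequence conservation profiles by position-specific
    independent counts (PSIC) together with substitution and physicochemical
    features, trains random-forest and gradient-boosting classifiers under
    nested cross-validation with Bayesian (TPE) hyperparameter search,
    explains them with exact tree Shapley attributions, benchmarks against
    external predictor score tables with bootstrap confidence intervals,
    and applies a consensus mean-score rule to reclassify variants of
    uncertain significance. A seeded synthetic-fixture generator emulates
    sequences, structures, alignments and comparator scores with planted
    class structure so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    generics,
    stats,
    utils,
    tools,
    ranger,
    xgboost,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
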