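Package: ribosense
Title: Analysis of Multiplexed Ribozyme Biosensor Selections from Cleavage Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the computational analysis of
    highly multiplexed RNA-biosensor (aptazyme) selections read out by
    cleavage sequencing. Covers the full desk pipeline: simulation of
    randomized hammerhead-ribozyme libraries and their ligand-dependent
    cleavage, design of pooled compound mixtures under mass-spectrometry
    non-overlap constraints, odds-ratio fold-change statistics with
    delta-method confidence intervals and Bonferroni significance calls,
    group-testing deconvolution of sensor-ligand assignments from pooled
    responses, response-profile clustering with a noise-scaled distance,
    cross-reactivity and dose-response summaries, fragment-based hit
    prediction with leave-one-out random forests, selection-round dynamics,
    and pooled LC-MS identity verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
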