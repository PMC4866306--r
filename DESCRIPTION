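Package: diallelGP
Title: Genomic and Phenomic Prediction of Quantitative Traits in Diallel Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and prediction toolkit for two-panel diallel crosses of
    haploid segregants, modelled on large yeast hybrid panels. Simulates
    recombinant haploid panels and their full diallel of diploid hybrids with
    configurable trait architectures (additive, dominance, epistatic and shared
    non-additive variance, replicated measurements); builds realized genomic
    relatedness matrices and identity-by-state summaries; classifies hybrid
    pairs into close (one shared haploid parent) and distant relatives; and
    implements a zoo of trait predictors: regression on other phenotypes,
    genomic BLUP with model-derived predictive standard deviations,
    forward-selection QTL models sized by nested cross-validation, linear mixed
    models with dominance and interaction terms, their phenotype-augmented
    variants, midparent prediction and a multi-trait mixed model with Kronecker
    covariance. Evaluation utilities run parent-split cross-validation,
    close/distant training scenarios, learning curves, training-set replacement
    and QTL/weight cross-fitting experiments, and calibration summaries of
    predictive uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
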