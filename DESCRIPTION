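Package: raremut
Title: Somatic Variant Richness and Unseen-Variant Probability Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for mining rare somatic variants in cancer
    mutation catalogs. Builds variant frequency-of-frequency vectors from
    MAF-style tables, estimates occurrence probabilities of seen and hitherto
    unseen variants with the Good-Turing estimator (Simple Good-Turing
    smoothing), extrapolates the expected number of new variants in future
    cohorts with a smoothed Good-Toulmin estimator, stratifies tumors into
    mutational-signature subgroups with scaled hypermutation thresholds,
    quantifies tissue-of-origin specificity by normalized mutual information
    against a permutation null, estimates gene-pair co-mutation and mutual
    exclusivity probabilities, and scores train/validate concordance with
    Lin's concordance correlation coefficient. Includes a synthetic cohort
    generator with exact ground-truth oracles for calibrating every estimator.
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
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    yaml
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
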