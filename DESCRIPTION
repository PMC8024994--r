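Package: tactileavatar
Title: Personalized Tactile Decision Avatars from Piezoelectric Touch and Slide Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates multiarray piezoelectric recordings of ranked texture
    materials (touch transients whose initial slope encodes durometer hardness,
    and sliding oscillations whose dominant frequency encodes surface pattern
    pitch), models individual human forced-ranking behaviour as noisy latent
    utilities, and trains a dual-branch neural network on per-material rank
    decision histograms so that its softmax output reproduces one person's
    tactile decisions. Includes the expected-decision rule with
    tolerance-bounded accuracy, human-avatar decision RMSE and kurtosis
    comparisons, leave-one-out evaluation on untrained materials, and
    simplex-constrained decomposition of an untrained histogram into trained
    histograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    arrow,
    jsonlite,
    optparse,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
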