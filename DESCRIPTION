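Package: soflr
Title: Driver Gene Set Size Estimation from Overlap-Decay Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Estimates the number of "driver" genes commonly activated across
    independently derived malignant transformants from the decay of the mean
    k-way overlap of activated-gene sets. Implements SOFLR (Sequentially
    Optimizing the Fitting of Linear Regression): an integer grid search for
    the asymptote d of the model y = d + T*p^x, selecting the d that maximizes
    the adjusted R-squared of the ordinary least squares fit of log(y - d) on
    the isolate count. Includes two-fold-change activation calling from
    expression matrices, exact combinatorial mean overlap curves, a Monte
    Carlo multi-set overlap significance test based on an iterated
    hypergeometric chain, a binomial passenger-gene simulation of the minimum
    isolate count, a four-parameter logistic comparator fit, required
    sample-size prediction, and a synthetic data generator for the
    driver/passenger/non-responsive model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite,
    minpack.lm,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
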