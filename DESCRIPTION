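Package: trophicstate
Title: Probabilistic Multi-Parameter Lake Trophic State Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Continuous, probabilistic classification of lake trophic state
    (oligotrophic, mesotrophic, eutrophic, hypereutrophic) with a
    proportional-odds ordered logistic regression over standardized log
    Secchi disk depth, log total nitrogen, log total phosphorus, and
    elevation.  Provides maximum-likelihood and Bayesian fitting of the
    ordinal model, a continuous trophic state index with per-class
    probabilities, random-forest variable selection, hold-out evaluation
    with balanced accuracy, a generative simulator for National Lakes
    Assessment style data, and a command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    randomForest
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
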