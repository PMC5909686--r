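Package: reeftransfer
Title: Transferability of Reef-Fish Abundance Models Between Reef Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and transferring predictive models of reef-fish
    abundance between reef systems surveyed by underwater visual census. Provides
    a synthetic twin-system generator with known generative parameters, scenario
    construction including a randomized transect-downscaling algorithm, a fixed
    candidate set of negative-binomial count models with a reef-level random
    intercept, AICc-weight multimodel inference with variance-explained and
    effect-size summaries, grouped cross-validation and Moran's I correlogram
    diagnostics, and a four-part metric suite quantifying how well a model fitted
    in one reef system predicts another.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    glmmTMB,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    ape,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
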