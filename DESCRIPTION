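Package: sitegada
Title: Site Index Models with Indicator-Variable, Mixed-Effects, GADA and
    g-GADA Parameterizations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits subject-specific height-age (site index) models for
    stem-analysis data using three base growth functions (Chapman-Richards,
    modified Hossfeld IV, Schumacher) crossed with four parameterizations of
    the tree-level (local) parameters: fixed-effect indicator variables,
    nonlinear mixed effects with a self-implemented marginal likelihood
    (Laplace, adaptive Gauss-Hermite, and first-order methods), the
    Generalized Algebraic Difference Approach (GADA), and the grounded GADA
    (g-GADA).  Includes maximum-likelihood fitting with profiled per-tree
    local parameters, AICc-based model comparison, age-binned error
    profiles, calibration of fitted population models to new trees with
    root screening, and a synthetic stem-analysis data generator for
    validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    numDeriv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
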