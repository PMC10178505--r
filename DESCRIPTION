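Package: uaeopt
Title: Response-Surface and Neural-Surrogate Optimization of
    Ultrasound-Assisted Extraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for modeling and optimizing ultrasound-assisted
    extraction of bioactive compounds with designed experiments. Builds
    rotatable central composite designs, fits second-order response-surface
    models in coded variables with lack-of-fit ANOVA, trains small
    tansig/linear feed-forward surrogate networks by Levenberg-Marquardt,
    optimizes a composite extraction objective with a real-coded genetic
    algorithm, and compares surrogate models with a suite of error
    statistics (RMSE, MSE, MPE, AAD, R-squared). Ships a complete 20-run
    garlic-leaf extraction dataset and a synthetic response-surface
    generator for property-based validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
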