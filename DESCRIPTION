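Package: nomolog
Title: Nomograms for Logistic Regression Models from Coefficients Alone
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs, renders, and numerically evaluates nomograms for
    logistic regression models given only the fitted coefficients and each
    predictor's plausible range, with no access to training data. Implements
    the point-assignment algorithm (affine value-to-points maps anchored by
    the most influential predictor), the probability-assignment algorithm
    (mapping the total point sum through the sigmoid over the linear
    predictor's attainable range, yielding an evenly scaled probability
    panel), type-aware axis layout (solid axes for continuous predictors,
    dashed for categorical, one-hot levels of a nominal variable merged onto
    a single axis), and a simulated-reader study layer that models graphical
    reading as tick rounding plus noise and summarises discrimination and
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    readxl,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xml2
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
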