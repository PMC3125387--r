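Package: expodesign
Title: Cost-Optimal Allocation of Exposure Measurements Under a Budget
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Design tools for exposure assessment studies that must buy
    precision with a fixed budget. Exposure is described by a hierarchical
    random-effects model (subjects, measurement occasions within subjects,
    sampling quanta within occasions) and data collection by power-law cost
    functions at each stage. The package finds the integer allocation of
    subjects and occasions that minimizes the variance of the estimated
    group mean exposure under the budget constraint, using closed-form
    screening rules where the cost functions are linear and exact integer
    enumeration otherwise, and reproduces a 225-scenario reference study of
    how non-linear costs reshape optimal designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
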