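Package: lionlen
Title: Length-Based, Age-Structured Growth Modelling for Invasive Lionfish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits length-based, age-structured population models to monthly
    length-frequency data, with traditional and seasonalized (Somers) von
    Bertalanffy growth, finite normal mixtures over length bins, maximum
    likelihood estimation with AICc model selection and Akaike weights,
    sensitivity and random-start robustness diagnostics, otolith annulus-age
    reconciliation, and a synthetic-data generator emulating a northeast
    Florida lionfish sampling programme. Tibble-first interfaces, broom-style
    tidiers and ggplot2 autoplot methods throughout.
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
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
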