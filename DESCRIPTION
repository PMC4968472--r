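Package: corvnet
Title: Social Networks and Network-Based Diffusion Analysis for Animal Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how information spreads through animal social
    groups. Builds weighted directed social networks from dyadic interaction
    event logs and scan samples, computes strength, eigenvector and
    Stephenson-Zelen information centrality, ranks linear dominance
    hierarchies by the I&SI method, performs MRQAP network regression with
    double-Dekker semipartialling permutation inference, and fits
    order-of-acquisition diffusion (OADA) models with AICc model averaging,
    network support ratios and the estimated proportion of socially
    transmitted acquisitions. A seeded synthetic-data generator produces
    group interaction streams and diffusions with known ground truth so the
    whole pipeline can be validated without field data.
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
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
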