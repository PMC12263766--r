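Package: ketomr
Title: Instrument Validity Premises for Mendelian Randomization of Ketone
    Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-sample Mendelian randomization toolkit built around a
    four-premise framework for selecting valid genetic instruments for
    ketone metabolism (acetone, acetoacetate, beta-hydroxybutyrate).
    Provides readers for GWAS summary statistics, gene annotations, LD
    matrices and trait-association catalogues; effect-allele harmonization
    with palindrome handling; gene-region windowing and greedy LD clumping;
    from-scratch ratio, inverse-variance weighted, MR-Egger and weighted
    median estimators with heterogeneity statistics; a stepwise premise
    pipeline producing pass/fail/not-evaluated verdict matrices; and a
    synthetic summary-statistics generator with known truth for testing
    every stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
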