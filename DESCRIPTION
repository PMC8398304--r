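Package: snpmr
Title: Single-Variant Two-Sample Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-sample Mendelian randomization with a single genetic
    instrument: Wald-ratio causal estimates from GWAS summary statistics,
    per-allele odds ratios with normal-theory confidence intervals,
    fixed-effects inverse-variance meta-analysis with Cochran's Q and I-squared
    heterogeneity statistics, effect-allele harmonization, and instrument
    strength diagnostics (variance explained, F statistic). Ships the
    lactase-persistence (rs4988235) milk-intake instrument and the
    neurodegenerative-disease outcome associations it was built around as a
    worked fixture, plus a synthetic two-sample case-control study generator
    for end-to-end parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils,
    yaml
Suggests:
    jsonlite,
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
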