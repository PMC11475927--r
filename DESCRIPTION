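Package: cnvconcord
Title: Multi-Platform Concordance Analysis of Gene Copy-Number Calls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Benchmarks agreement between laboratory platforms that genotype
    gene copy-number variation (CNV) in paired tumor/normal samples, such as
    SNP microarrays, hybridization-based CNV panels, and droplet digital PCR.
    Provides discretization of quantitative copy numbers into three-state
    calls, prevalence- and bias-adjusted kappa (PABAK) agreement matrices,
    Passing-Bablok regression with proportional/constant bias classification
    and a relative-discrepancy statistic, per-gene tumor-vs-normal testing
    with paired Wilcoxon tests pooled by harmonic mean and Holm-corrected
    across genes, normal-tissue quality filters, a seeded multi-platform
    cohort simulator with known truth, and an end-to-end pipeline that emits
    tidy, reproducible report tables.
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
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
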