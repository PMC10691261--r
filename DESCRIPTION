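Package: tidybmd
Title: Transcriptomic Benchmark-Dose Modeling and Pathway Points of Departure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy workflow for deriving transcriptomic points of departure
    from dose-response count experiments. Provides negative-binomial
    differential expression against vehicle controls with Benjamini-Hochberg
    false discovery control, ANOVA plus fold-change prefiltering of
    dose-responsive genes, per-gene benchmark-dose (BMD) estimation over a
    suite of dose-response models (linear, quadratic and cubic polynomials,
    power, Hill) with nested likelihood-ratio and AIC model selection,
    profile-likelihood BMDL/BMDU confidence bounds and quality-control
    rejection rules, Fisher-exact gene-set enrichment with pathway-level
    BMD aggregation, cross-chemical intersection and network summaries, and
    a seeded negative-binomial simulator with analytically known true BMDs
    for validation.
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
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
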