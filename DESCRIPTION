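Package: cyp2c9mr
Title: CYP2C9 Genotype-Phenotype Correlation Analysis with a Flurbiprofen
    Metabolic Ratio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates allele-specific contributions to a urinary metabolic
    ratio (4'-hydroxyflurbiprofen over flurbiprofen) with a zero-intercept
    additive allele regression, derives genotype-level activity estimates and
    their standard errors, compares genotype groups with heteroscedastic
    (Welch) ANOVA and Tamhane T2 post-hoc tests, translates fitted activities
    into genotype-guided dose adjustments, and quantifies how within-genotype
    variability limits genotype-only dosing. Includes cohort file readers with
    limit-of-quantification filtering, fitting from per-genotype summary
    statistics (sufficient-statistic normal equations), and a seeded
    Hardy-Weinberg cohort simulator so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
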