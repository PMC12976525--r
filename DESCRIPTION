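Package: targetmr
Title: Drug-Target Mendelian Randomization with Colocalization and
    Summary-Statistics Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for drug-target two-sample Mendelian randomization from
    GWAS/QTL summary statistics: cis-window instrument selection with
    Bonferroni or fixed significance rules and greedy LD clumping, allele
    harmonization, an estimator battery (Wald ratio, inverse-variance
    weighted, MR-Egger, weighted median, weighted mode, radial and
    PRESSO-style outlier procedures), Steiger directionality and
    binary-trait power calculations, two-step mediation with instrument
    stratification, Bayesian five-hypothesis colocalization via approximate
    Bayes factors, and a ground-truth generator for LD-structured
    cis-region summary statistics used to validate the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
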