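Package: moralcni
Title: Multinomial Processing-Tree Analysis of Moral Dilemma Judgments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing binary moral-dilemma judgments collected with
    the 24-item battery that crosses six base dilemmas with norm type
    (proscriptive vs. prescriptive) and consequence type (benefits greater or
    smaller than costs). Implements the CNI multinomial processing-tree model
    (sensitivity to consequences C, sensitivity to moral norms N, general
    inaction preference I) with maximum-likelihood estimation on pooled
    count tables, likelihood-ratio (G-squared) goodness-of-fit and nested
    parameter tests, Wald and profile confidence intervals, the
    process-dissociation decomposition into utilitarian (U) and deontological
    (D) inclinations, and the classical companion analyses (choice scores,
    one-sample t-tests, correlations, hierarchical regression with R-squared
    change, Cronbach's alpha, median splits). A seeded synthetic-data
    generator emulates a chronic-stress questionnaire study design and
    supports parameter-recovery and calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
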