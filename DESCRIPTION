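Package: concord7
Title: Concordance and Outcome Analysis of Endangered Species Act Section 7 Consultations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing administrative records of consultations
    conducted under section 7 of the U.S. Endangered Species Act, in which
    federal action agencies propose effect determinations for listed species
    and an expert wildlife agency issues the final determination.  Provides a
    cleaning and recoding pipeline for consultation exports, ordinal
    discrepancy scoring of paired agency/expert determinations, weighted
    Cohen's kappa and per-agency Kolmogorov-Smirnov deviation tests,
    frequency and trend analyses of consultation outcomes, fixed-margin
    permutation tests for species-by-work-type jeopardy enrichment, pairwise
    co-jeopardization analysis under a hypergeometric null, and a synthetic
    consultation-record generator so that every stage is testable without
    access to the underlying tracking database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
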