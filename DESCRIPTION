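Package: capbws
Title: Best-Worst Scaling Valuation of the OxCAP-MH Capability Instrument
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for eliciting relative preference weights for the 16 items
    of the OxCAP-MH capability wellbeing instrument from object-case
    best-worst scaling (MaxDiff) surveys. Provides balanced incomplete block
    design generation for choice tasks, a synthetic-respondent simulator with
    cohort-structured preference heterogeneity, hierarchical Bayes estimation
    of individual item utilities with root-likelihood fit diagnostics and
    exclusion of inconsistent responders, relative importance scores, cohort
    comparisons (rank orders, Kruskal-Wallis tests, Pearson correlation
    matrices), per-item regressions with jackknife robust variances based on
    leave-one-participant-out re-estimation, and construction of an anchored
    0-1 preference weight set for scoring capability states.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
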