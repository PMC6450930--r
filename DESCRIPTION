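Package: rpindex
Title: Revealed-Preference Inconsistency Indices for Budget-Line Choice
    Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Consistency analysis for choice data from linear budget-set
    experiments (two-account 50/50 lottery allocations on graphical budget
    lines). Tests the Generalized Axiom of Revealed Preference (GARP) at
    any efficiency level, computes the Afriat critical-cost-efficiency
    index and the parametric Money Metric Index under disappointment-
    aversion utility with CRRA or CARA curvature, and derives leave-one-out
    trial-specific inconsistency indices that score the severity of each
    individual choice. Includes a synthetic task generator with standard
    chooser strategies, a choice-simplicity (difficulty) index for
    continuous budget sets, and a neural random utility simulator with
    skewed valuation noise, noise calibration to a target inconsistency
    level, and a pooled noise-versus-inconsistency correlation diagnostic.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
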