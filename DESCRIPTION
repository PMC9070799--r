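Package: lcrab
Title: Low-Complexity Regions and Protein and Transcript Abundance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how low-complexity regions (LCRs) in protein
    sequences associate with transcript and protein abundance. Implements
    windowed Shannon-entropy LCR detection with SEG-style two-threshold
    trigger/extend regions and homopolymer classification; per-gene abundance
    integration across tissues with the tau tissue-specificity index,
    post-mortem ischemia-time adjustment, and degradation-rate aggregation;
    the Time-Weighted normalized Translation Efficiency (TWnTE) model of
    codon-level tRNA supply and demand with wobble-constraint and
    perturbability/resupply fitting by Nelder-Mead; quartile-shift
    permutation tests with labelled variants and a rank-sum check; logistic
    regression of LCR status on abundance with standardized coefficients and
    per-doubling odds; and a synthetic proteome/transcriptome generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
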