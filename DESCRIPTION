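Package: mirnapair
Title: Association Measures for miRNA-mRNA Pairs from Matched and Unmatched Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies microRNA-mRNA pairs of potential regulatory interest by
    integrating putative target predictions with expression data. Implements two
    association measures: an unmatched-data (UD) measure that discretizes
    per-condition differential-expression calls into {-1, 0, +1}, summarizes a
    pair as a 3x3 contingency table over biological conditions, and assesses
    significance with an exact multinomial goodness-of-fit test against a
    pooled-resampling null; and a matched-data (MD) measure that estimates the
    change in mRNA expression per unit change in miRNA expression as a
    through-origin regression slope on change-in-expression values and obtains a
    left-tail permutation p-value from pseudo-mRNA profiles. Includes
    differential-expression preprocessing, opposite-direction target filters,
    Benjamini-Hochberg correction, a Pearson-correlation permutation comparator,
    a synthetic-data generator with planted regulatory pairs, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
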