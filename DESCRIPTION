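Package: interplay2x2
Title: Classifying Forms of Interplay in 2x2 Combined-Intervention Expression Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Taxonomy-driven hypothesis testing for 2x2 factorial
    combination experiments on log2 expression data. Every feature is
    classified into one of ten forms of interplay between a combined
    manipulation and its single constituents (synergism, additivity,
    antagonism, potentiation, redundance, reductive and emergent
    effects), in up- and down-regulated variants, by compounding
    one-sided moderated contrast tests and two-one-sided-tests (TOST)
    equivalence tests through an intersection-union test. Per-feature
    variances are shrunk by an empirical Bayes procedure before
    testing. Includes a synthetic-data generator with planted interplay
    patterns for recovery and size studies, TSV readers and writers,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
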