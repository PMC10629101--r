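Package: barcodeval
Title: Evaluation of DNA Barcodes for Discriminating Closely Related Species
Version: 0.1.0
Authors@R:
    person("Barcode", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A workflow for evaluating candidate DNA barcode regions (single
    and concatenated markers) for the discrimination of two closely related
    species. Implements Kimura two-parameter pairwise distances with group
    summaries (mean inter- and intraspecific distance, theta, coalescence
    depth), barcoding-gap assessment from distance distributions, Wilcoxon
    signed-rank comparison of interspecific distances between markers,
    induction and scoring of diagnostic character rules (conjunctive logic
    formulae with cc/wc/nc rates), best-match identification against a local
    reference library, neighbor-joining trees with nonparametric bootstrap and
    a species-monophyly criterion, and a seeded two-species sequence simulator
    so the whole pipeline can be exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
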