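Package: tmcoffee
Title: Consistency-Based Multiple Sequence Alignment of Transmembrane Proteins
    with Homology Extension
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Aligns alpha-helical transmembrane protein families with a
    consistency-based strategy: each input sequence is extended into a
    position-wise profile from filtered database-search hits, every pair of
    profiles is aligned with a bi-phasic-gap pair hidden Markov model whose
    forward-backward posteriors feed a T-Coffee-style constraint library,
    the library is relay-extended through third sequences, and a progressive
    aligner maximises extended-library consistency. Includes BAliBASE-style
    sum-of-pairs (SP) and total-column (TC) scoring restricted to annotated
    core blocks, an exact paired signed-rank test for method comparison, a
    synthetic transmembrane-family generator with tracked ground truth, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    parallel,
    Rcpp,
    stats,
    tools,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
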