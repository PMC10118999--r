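Package: mosaictr
Title: Decomposition of Mosaic Tandem Repeats in DNA Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes mosaic tandem repeats (regions built from runs of
    several distinct repeat units) in DNA sequences. Candidate repeat units
    are enumerated as repetitive non-self-overlapping substrings using a
    suffix array, LCP array and Morris-Pratt border arrays; a parsimonious
    unit set is then chosen greedily under an extended penalty that balances
    unit inventory size, copy counts and coverage; finally the sequence is
    decomposed against the selected units by error-tolerant wraparound
    dynamic programming (approximate matching against (u1|...|uk)*).
    Includes a synthetic mosaic-repeat benchmark with configurable
    sequencing-error injection and copy-count accuracy scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
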