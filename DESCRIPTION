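Package: scskit
Title: Frequency-Based Linguistic Analysis of Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Treats protein amino-acid sequences as sentences built from short
    constituent sequences (SCSs, k-mers of length 3-5) and analyses their usage
    the way quantitative linguistics analyses words. Computes real counts,
    expected counts under positional independence, and availability scores
    A = (R - E)/E over a corpus; per-residue availability profiles of a query
    sequence; species-specific SCS extraction by availability or rank distance;
    a triplet "idiom" grammar (core/sub triplet co-occurrence within a +/-10
    window, with evaluation scores), sequence annotation and greedy de-novo
    sequence design; and rank-frequency (Zipf) analysis of SCSs and English
    text. Includes a seeded synthetic-corpus generator with planted enriched,
    forbidden, and idiomatically linked SCSs for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
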