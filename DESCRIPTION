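Package: koplr
Title: Lysine-Oriented Peptide Library Screens and PSSM Proteome Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis of lysine-oriented peptide library (K-OPL) screens of
    lysine methyltransferases. Models the combinatorial library (one set per
    flanking position and fixed residue around a central lysine), turns
    replicate counts-per-minute readouts into a normalized, log-transformed
    position-specific scoring matrix, scores every lysine-centered 7-mer in a
    proteome, ranks and thresholds candidates at a top fraction, predicts the
    activity ordering of peptide variants, and merges candidates with
    user-supplied annotations. A synthetic-data module generates screens with
    planted selectivity profiles and toy proteomes with planted motifs so the
    full pipeline can be benchmarked against known ground truth.
License: MIT
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
    methods,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
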