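Package: utrlen
Title: Genomic Determinants of 5'UTR Length
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies how per-sequence genomic features shape the lengths of
    5' untranslated regions (5'UTRs) in eukaryotic transcripts. Computes
    composition features per 5'UTR (G+C content, observed-to-expected ratios
    of the start trinucleotide AUG, the stop trinucleotides UGA/UAA/UAG, and
    the CG/UG/UU/UA dinucleotides, plus upstream open reading frame presence),
    applies a zero-OE-ratio cleaning rule, and models log10 5'UTR length by
    multiple linear regression with backward elimination, variance inflation
    factor screening, partial correlations, and a relative-contribution-to-
    variability-explained (RCVE) importance decomposition. Includes a
    synthetic 5'UTR generator with planted length-feature relationships so
    every pipeline stage can be validated without external sequence databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    car,
    nortest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
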