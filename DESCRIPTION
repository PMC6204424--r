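Package: spliceatlas
Title: Alternative-Splicing Atlas Construction with Evolutionary Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds genome-wide alternative-splicing (AS) atlases from
    transcript models: extraction, classification (intron retention,
    alternative 5'/3' splice sites, exon skipping, other) and deduplication
    of AS events from isoform intron chains; donor/acceptor dinucleotide
    typing of splice sites; the fractional tissue-specificity statistic
    maxTs; phylostratigraphic assignment of genes to age strata from an
    ortholog table and a dated species tree, with stratified AS and
    transposable-element summaries; homology-filter gene-family
    identification and Nei-Gojobori (1986) synonymous-rate estimation with
    Ks-based divergence dating. Ships a deterministic synthetic-data
    generator with planted ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
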