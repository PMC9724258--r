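Package: trnabarcode
Title: Family-Exclusive COI Barcode Primer Discovery from Flanking tRNA Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers PCR primer pairs for amplifying the mitochondrial COI
    barcode region that are exclusive to taxonomic family groups. Primers are
    placed inside the tRNA genes flanking COI rather than inside COI itself, so
    that the amplicon spans the full barcode. The package parses annotated
    mitogenomes (GenBank flat files or FASTA plus feature tables), extracts
    k-th nearest flanking tRNA segments with circular-topology support, scores
    pairwise sequence similarity on a 0-1000 scale, enumerates and ranks primer
    candidates under Primer3-style length/Tm/GC constraints, performs
    mismatch-tolerant in-silico PCR across a genome universe, selects minimal
    primer-pair covers for multispecies groups, and orchestrates a two-stage
    resolution strategy (candidate cycling, flank extension, similarity-based
    re-grouping, then per-species resolution). A seeded synthetic-mitogenome
    generator emulates family structure, confusable flank pairs, missing
    flanks, and oversized families so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    methods,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
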