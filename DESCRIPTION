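Package: barcodeDx
Title: Species-Diagnostic DNA Barcoding Assays from Labeled Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building species-diagnostic DNA-barcoding assays from
    species-labeled barcode panels (rbcL, matK, ITS2, trnH-psbA and similar
    loci). Reads and writes FASTA and Clustal alignments, computes per-locus
    barcode descriptors (ungapped length, GC content, columnwise percent
    variation), detects species-diagnostic nucleotide sites and motifs in a
    labeled multiple alignment, designs allele-specific (ARMS) multiplex PCR
    primer panels anchored with their 3' termini on diagnostic motifs together
    with a universal internal amplification control, predicts multiplex PCR
    products in silico under a 3'-seed mismatch model, renders virtual gel
    lanes and classifies band patterns into species calls, and clusters
    barcodes with Kimura two-parameter distances, neighbor-joining trees and
    nonparametric bootstrap support. Includes a seeded synthetic panel
    simulator with planted, known-truth diagnostic structure so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    seqinr,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
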