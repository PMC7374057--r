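Package: codonsel
Title: Selection on Synonymous Codon Usage Across Prokaryotic Gene Sets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify how translational selection shapes synonymous
    codon usage across prokaryotic gene sets of increasing ancestry
    (singletons, core gene sets C1..Cn, putative highly expressed genes).
    Implements raw codon counting and usage statistics (CUF, RSCU, GC3,
    Wright's effective number of codons), modal codon usage estimation with
    artificial modal sequences, correspondence analysis of genes-by-codons
    tables with centroid and supplementary-row projection, the tRNA
    adaptation index with trainable wobble pairing weights (Sij) fitted by
    maximizing the Spearman correlation between DCBS and tAI, C/U third-base
    bias statistics and genome group classification, extraction of conserved
    and variable intragenic codon domains from ortholog alignments for
    highly/lowly expressed gene subsets, codon-usage distance matrices with
    neighbor-joining trees, and a synthetic-data generator including an M0
    (F3x4) codon-substitution simulator with Nei-Gojobori KA/KS estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
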