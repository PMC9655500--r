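Package: nodpep
Title: Annotation and Expression Analysis of Nodule-Specific
    Cysteine-Rich Peptide Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery and classification of nodule-specific
    cysteine-rich (NCR) and defensin-like peptide genes in annotated
    legume genomes by cysteine-spacing motif scanning, signal-peptide
    heuristics and exon-structure rules; isoelectric-point computation
    by charge-curve bisection with cationic/anionic classification;
    a quantile-normalization plus per-gene ANOVA differential-expression
    pipeline for nodulated (Nod+) versus uninoculated (Nod-) root
    transcriptomes; hypergeometric GO-term enrichment; and a
    synthetic-data generator emitting genomes, gene models and count
    matrices with planted ground truth so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    limma,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
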