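Package: strainref
Title: Strain-Specific Reference Genomes and Reference-Bias Statistics for
    Recombinant Inbred RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for strain-aware RNA-seq analysis in recombinant inbred
    mouse panels such as BXD. Delineates donor-strain haplotype blocks from
    panel genotype tables, imputes dense strain-specific variants into each
    line, builds per-line custom reference genomes with UCSC chain files and
    coordinate liftover of annotation, and provides the downstream
    statistics: count filtering and TMM/log2-cpm normalization, a paired
    moderated-t differential-mapping test between references, permutation
    based local (cis) eQTL detection with Storey q-values, and the
    reference-bias skewness and eQTL-similarity summaries. Includes a
    synthetic-data generator with a planted ground-truth ledger and an
    injectable allele-loss mechanism emulating reference bias.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    data.table,
    edgeR,
    stats,
    utils,
    vcfR
Suggests:
    GenomicRanges,
    jsonlite,
    limma,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
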