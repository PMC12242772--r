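Package: terraseq
Title: Annotation and Quantification of Telomeric Repeat-Containing RNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying telomeric repeat-containing RNA (TERRA) from
    genome assemblies and RNA sequencing data. Detects telomeric repeat
    tracts (terminal and interstitial) in assemblies and in noisy long
    reads, finds tandem arrays of the 61, 29 and 37 bp subtelomeric
    promoter elements, calls TERRA transcription regions from coverage
    enrichment, long-read 5' ends and CAGE tags and classifies them into
    Types I, II and III, counts RNA-seq fragments over the regions under
    mode-specific mapping-quality and duplicate filters, normalizes merged
    gene and TERRA count tables by smooth quantile normalization, and
    analyzes poly(A)+/- partitioning of TERRA transcripts. A synthetic-data
    generator produces mini-genomes, reads, evidence tracks and ground
    truth so that the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
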