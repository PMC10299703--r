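Package: ProteoformTools
Title: Proteoform Inference from Splice Isoforms, Epitope Maps, and Spectral Counts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing the protein products of a structurally
    complex gene locus. Builds spliced transcript sequences from a genome and
    exon models, enumerates AUG-initiated open reading frames, and collapses
    translations into a catalog of distinct protein isoforms grouped by
    N-terminal class (including isoforms nested at internal methionines).
    Compares allele sequence pairs for amino acid substitutions and indels,
    detects variant-induced 5' extensions of coding ORFs, and maps antibody
    antigen peptides onto isoforms to derive detection-specificity matrices.
    Quantifies proteoform evidence from peptide spectral counts: per-sample
    relative abundance profiles, phosphosite occupancy, N-terminal truncation
    boundary inference by step-model fitting, and assignment of gel bands to
    full-length or truncated isoform candidates. Includes a seeded synthetic
    data generator with serialized ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite
Suggests:
    seqinr,
    withr,
    testthat (>= 3.0.0)
biocViews: Proteomics, MassSpectrometry, AlternativeSplicing, Sequencing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
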