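Package: pepmapr
Title: Peptide-to-Genome Proteogenomic Mapping by Six-Frame Translated
    Local Alignment
Version: 0.1.0
Authors@R:
    person("pepmapr", "developers", email = "pepmapr@example.org",
           role = c("aut", "cre"))
Description: Maps mass-spectrometry-identified peptides onto genomic DNA to
    validate and refine gene-model annotations. Provides Smith-Waterman
    affine-gap local alignment of peptides against all six reading-frame
    translations of a genome (tBLASTn-style, with Karlin-Altschul e-values
    and 25-column tabular output), exact spliced amino-acid-to-genomic
    coordinate conversion through annotated gene models including genomic
    frame shifts across introns, classification of mapped peptides against
    High/Low-Confidence gene annotations, frame-shift-aware stitching of
    partial hits, an alignment-parameter evaluation harness, peptide
    physicochemical properties, standard-format exports (BED6/BED12, Circos
    tracks, summary tables), and a seeded synthetic genome/annotation/peptide
    generator with exact ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
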