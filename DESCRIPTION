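Package: hgvsConcord
Title: Concordance Analysis of HGVS Variant Nomenclature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying agreement between transcript- and
    protein-level variant descriptions (HGVS nomenclature) produced by
    annotation pipelines and curated variant databases. Implements a toy
    genome/transcript coordinate model with transcript-versus-genome
    reference differences, a dialect-tolerant parser and preferred-syntax
    formatter for coding (c.) and protein (p.) HGVS, allele normalization on
    both conventions (VCF-style left alignment and HGVS 3'-shifting with the
    intron-exon boundary exception, duplication detection, and
    deletion-insertion reduction), phased multinucleotide-variant merging,
    projection of genomic variants onto transcripts with Sequence Ontology
    effect terms, an exact/equivalent/incorrect/not-assessed match
    classifier gated on transcript accession and version, dataset-scale
    concordance summaries by variant type, and a synthetic-data generator
    that plants repeat contexts and injects the error modes observed in
    real annotation databases at configurable rates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
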