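## VCF 4.2 reader/writer (VariantAnnotation) for the plain variant-table
## representation.  Phase groups travel in the PGRP INFO tag (documented
## here rather than via genotype phase sets: the fixture VCFs carry no
## samples).

#' Read variants from a VCF file
#'
#' Multi-allelic records are expanded to one row per alternative allele.
#'
#' @param path VCF file.
#' @return variant table (contig, pos, ref, alt, id, phaseGroup).
#' @export
readVcfVariants <- function(path) {
  vcf0 <- VariantAnnotation::readVcf(path)
  ids0 <- rownames(vcf0)
  reps <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf0))
  vcf <- VariantAnnotation::expand(vcf0)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ids <- if (is.null(ids0)) rep(NA_character_, length(rr))
         else rep(ids0, reps)
  ## readVcf falls back to "chrom:pos_ref/alt" labels for missing IDs
  ids[is.na(ids) | ids == "." | ids == "" |
        grepl("^[^:]+:[0-9]+_", ids)] <- NA_character_
  pg <- if ("PGRP" %in% names(VariantAnnotation::info(vcf)))
    as.character(VariantAnnotation::info(vcf)$PGRP)
  else rep(NA_character_, length(rr))
  pg[pg %in% c(".", "")] <- NA_character_
  variantTable(as.character(GenomicRanges::seqnames(rr)),
               GenomicRanges::start(rr),
               as.character(VariantAnnotation::ref(vcf)),
               as.character(VariantAnnotation::alt(vcf)),
               id = ids, phaseGroup = pg)
}

#' Write variants to a VCF file
#'
#' @param variants variant table.
#' @param path output file (plain text VCF).
#' @param genome named [Biostrings::DNAStringSet] supplying contig lengths.
#' @return the path, invisibly; the written file round-trips through
#'   [readVcfVariants()].
#' @export
writeVcfVariants <- function(variants, path, genome) {
  n <- nrow(variants)
  ids <- variants$id
  ids[is.na(ids)] <- "."
  rr <- GenomicRanges::GRanges(
    seqnames = variants$contig,
    ranges = IRanges::IRanges(start = variants$pos,
                              width = nchar(variants$ref)))
  names(rr) <- ids
  GenomeInfoDb::seqlevels(rr) <- names(genome)
  GenomeInfoDb::seqlengths(rr) <- lengths(genome)
  pg <- variants$phaseGroup
  fixed <- S4Vectors::DataFrame(
    REF = Biostrings::DNAStringSet(variants$ref),
    ALT = Biostrings::DNAStringSetList(as.list(variants$alt)),
    QUAL = rep(NA_real_, n),
    FILTER = rep(".", n))
  info <- S4Vectors::DataFrame(PGRP = pg)
  hdr <- VariantAnnotation::VCFHeader(
    samples = character(),
    header = IRanges::DataFrameList(
      fileformat = S4Vectors::DataFrame(Value = "VCFv4.2",
                                        row.names = "fileformat"),
      INFO = S4Vectors::DataFrame(
        Number = "1", Type = "String",
        Description = "Phase group label; adjacent SNVs sharing a label are merged as a block substitution",
        row.names = "PGRP")))
  vcf <- VariantAnnotation::VCF(rowRanges = rr, fixed = fixed,
                                info = info, collapsed = TRUE)
  VariantAnnotation::header(vcf) <- hdr
  VariantAnnotation::writeVcf(vcf, path)
  invisible(path)
}
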