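## FASTA (Biostrings) and GFF3 (rtracklayer) interfaces for the fixture
## genome and transcript models.  Transcript overrides travel in a dedicated
## `overrides` attribute on the mRNA feature ("gpos:base|gpos:base",
## transcript-strand bases).

#' Read a fixture genome from FASTA
#' @param path FASTA file.
#' @return named [Biostrings::DNAStringSet] (names truncated to the first
#'   token).
#' @export
readGenome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a fixture genome to FASTA
#' @param genome named [Biostrings::DNAStringSet].
#' @param path output file.
#' @export
writeGenome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

## Genomic spans of the CDS (one range per coding exon segment).
.cdsGenomicRanges <- function(tx) {
  str <- .txStructure(tx)
  idx <- str$idxByTpos[tx@cdsStart:tx@cdsEnd]
  g <- sort(vapply(idx, str$gposOfIdx, integer(1L)))
  brk <- which(diff(g) != 1L)
  starts <- g[c(1L, brk + 1L)]
  ends <- g[c(brk, length(g))]
  IRanges::IRanges(start = starts, end = ends)
}

#' Write transcript models to GFF3
#'
#' Emits standard mRNA/exon/CDS features; reference overrides are carried in
#' a dedicated `overrides` attribute on the mRNA record.
#'
#' @param transcripts list of [TranscriptModel]s.
#' @param path output GFF3 file.
#' @export
writeTranscriptsGff3 <- function(transcripts, path) {
  grs <- lapply(transcripts, function(tx) {
    id <- txId(tx)
    ov <- tx@overrides
    ovTxt <- if (nrow(ov))
      paste(paste0(ov$gpos, ":", ov$base), collapse = "|")
    else NA_character_
    nE <- length(tx@exons)
    cds <- .cdsGenomicRanges(tx)
    n <- 1L + nE + length(cds)
    gr <- GenomicRanges::GRanges(
      seqnames = tx@contig,
      ranges = c(IRanges::IRanges(min(IRanges::start(tx@exons)),
                                  max(IRanges::end(tx@exons))),
                 tx@exons, cds),
      strand = tx@strand)
    ## CDS phase: bases of the previous segments modulo 3, in transcript
    ## order (segments are stored in ascending genomic order)
    w <- IRanges::width(cds)
    cum <- cumsum(c(0L, w))[seq_along(w)]
    if (tx@strand == "-") cum <- rev(cumsum(c(0L, rev(w)))[seq_along(w)])
    phase <- (3L - cum %% 3L) %% 3L
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      type = c("mRNA", rep("exon", nE), rep("CDS", length(cds))),
      phase = c(NA_integer_, rep(NA_integer_, nE), phase),
      ID = c(id, paste0(id, ":exon", seq_len(nE)),
             paste0(id, ":cds", seq_along(cds))),
      Parent = c(NA_character_, rep(id, nE + length(cds))),
      gene = c(tx@gene, rep(NA_character_, nE + length(cds))),
      overrides = c(ovTxt, rep(NA_character_, nE + length(cds))))
    gr
  })
  all <- suppressWarnings(do.call(c, unname(grs)))
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' Read transcript models from GFF3
#'
#' @param path GFF3 with mRNA/exon/CDS features as written by
#'   [writeTranscriptsGff3()].
#' @return named list of [TranscriptModel]s keyed by `accession.version`.
#' @export
readTranscriptsGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  parent <- vapply(as.list(mc$Parent), function(p)
    if (length(p)) as.character(p)[1L] else NA_character_, character(1L))
  mrna <- which(mc$type == "mRNA")
  out <- list()
  for (i in mrna) {
    id <- as.character(mc$ID[i])
    acc <- sub("\\.[0-9]+$", "", id)
    ver <- as.integer(sub("^.*\\.", "", id))
    children <- which(!is.na(parent) & parent == id)
    exonIdx <- children[mc$type[children] == "exon"]
    cdsIdx <- children[mc$type[children] == "CDS"]
    exons <- IRanges::IRanges(
      start = sort(GenomicRanges::start(gr[exonIdx])),
      end = sort(GenomicRanges::end(gr[exonIdx])))
    strand <- as.character(GenomicRanges::strand(gr[i]))
    ovTxt <- if ("overrides" %in% names(mc)) mc$overrides[i] else NA
    overrides <- data.frame(gpos = integer(), base = character())
    if (!is.na(ovTxt) && nzchar(ovTxt)) {
      parts <- strsplit(strsplit(as.character(ovTxt), "|",
                                 fixed = TRUE)[[1L]], ":", fixed = TRUE)
      overrides <- data.frame(
        gpos = vapply(parts, function(p) as.integer(p[1L]), integer(1L)),
        base = vapply(parts, function(p) p[2L], character(1L)))
    }
    gene <- if ("gene" %in% names(mc)) as.character(mc$gene[i]) else NA
    tmp <- TranscriptModel(acc, ver, if (is.na(gene)) "" else gene,
                           as.character(GenomicRanges::seqnames(gr[i])),
                           strand, exons, cdsStart = 1L,
                           cdsEnd = sum(IRanges::width(exons)),
                           overrides = overrides)
    ## recover transcript-coordinate CDS bounds from the CDS genomic spans
    str <- .txStructure(tmp)
    cdsG <- sort(c(GenomicRanges::start(gr[cdsIdx]),
                   GenomicRanges::end(gr[cdsIdx])))
    gLo <- min(cdsG); gHi <- max(cdsG)
    tp <- sort(c(str$tpos[str$idxOfGpos(gLo)], str$tpos[str$idxOfGpos(gHi)]))
    out[[id]] <- TranscriptModel(acc, ver, if (is.na(gene)) "" else gene,
                                 tmp@contig, strand, exons,
                                 cdsStart = tp[1L], cdsEnd = tp[2L],
                                 overrides = overrides)
  }
  out
}
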