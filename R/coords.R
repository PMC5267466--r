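## Genomic <-> transcript <-> CDS coordinate plumbing.
##
## Internally everything runs in "locus index" space: position 1 is the 5'
## end of the transcript locus (first exon base), increasing in transcript
## direction and covering introns, so strand handling and intron offsets
## reduce to integer arithmetic on one axis.  VCF and HGVS surfaces stay
## 1-based inclusive.

## Structure-only view of a transcript (no genome needed).
.txStructure <- function(tx) {
  ex <- tx@exons
  nE <- length(ex)
  locusStart <- min(IRanges::start(ex))
  locusEnd <- max(IRanges::end(ex))
  L <- locusEnd - locusStart + 1L
  plus <- tx@strand == "+"
  idxOfGpos <- function(g) if (plus) g - locusStart + 1L else locusEnd - g + 1L
  gposOfIdx <- function(i) if (plus) locusStart + i - 1L else locusEnd - i + 1L

  region <- integer(L)
  txOrder <- if (plus) seq_len(nE) else rev(seq_len(nE))
  for (j in seq_len(nE)) {
    e <- txOrder[j]
    i1 <- idxOfGpos(if (plus) IRanges::start(ex)[e] else IRanges::end(ex)[e])
    i2 <- idxOfGpos(if (plus) IRanges::end(ex)[e] else IRanges::start(ex)[e])
    region[i1:i2] <- j
  }
  introns <- list()
  k <- 0L
  i <- 1L
  while (i <= L) {
    if (region[i] == 0L) {
      k <- k + 1L
      j <- i
      while (j < L && region[j + 1L] == 0L) j <- j + 1L
      region[i:j] <- -k
      introns[[k]] <- list(startIdx = i, endIdx = j, len = j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  tpos <- rep(NA_integer_, L)
  exonic <- which(region > 0L)
  tpos[exonic] <- seq_along(exonic)
  idxByTpos <- exonic
  list(tx = tx, plus = plus, locusStart = locusStart, locusEnd = locusEnd,
       L = L, region = region, tpos = tpos, idxByTpos = idxByTpos,
       txLen = length(exonic), introns = introns,
       idxOfGpos = idxOfGpos, gposOfIdx = gposOfIdx)
}

.anchorOfTpos <- function(tp, cdsStart, cdsEnd) {
  if (tp < cdsStart) CdsCoord(tp - cdsStart)
  else if (tp > cdsEnd) CdsCoord(tp - cdsEnd, star = TRUE)
  else CdsCoord(tp - cdsStart + 1L)
}

.tposOfAnchor <- function(coord, cdsStart, cdsEnd) {
  if (coord@star) cdsEnd + coord@anchor
  else if (coord@anchor < 0L) cdsStart + coord@anchor
  else cdsStart + coord@anchor - 1L
}

.coordOfIdx <- function(str, i, cdsStart, cdsEnd) {
  r <- str$region[i]
  if (r > 0L)
    return(.anchorOfTpos(str$tpos[i], cdsStart, cdsEnd))
  intr <- str$introns[[-r]]
  j <- i - intr$startIdx + 1L
  if (j <= ceiling(intr$len / 2)) {
    up <- .coordOfIdx(str, intr$startIdx - 1L, cdsStart, cdsEnd)
    new("CdsCoord", anchor = up@anchor, star = up@star, offset = j)
  } else {
    dn <- .coordOfIdx(str, intr$endIdx + 1L, cdsStart, cdsEnd)
    new("CdsCoord", anchor = dn@anchor, star = dn@star,
        offset = -(intr$len - j + 1L))
  }
}

.idxOfCoord <- function(str, coord, cdsStart, cdsEnd) {
  tp <- .tposOfAnchor(coord, cdsStart, cdsEnd)
  if (is.na(tp) || tp < 1L || tp > str$txLen)
    stop(.outOfTranscript("anchor outside the modeled transcript"))
  i <- str$idxByTpos[tp] + coord@offset
  if (i < 1L || i > str$L)
    stop(.outOfTranscript("offset outside the modeled introns"))
  if (coord@offset != 0L) {
    span <- (str$idxByTpos[tp] + sign(coord@offset)):i
    if (any(str$region[span] >= 0L))
      stop(.outOfTranscript("intron offset crosses an exon boundary"))
  }
  i
}

#' Map a genomic position to an HGVS coding coordinate
#'
#' Intronic positions are anchored to the nearest exon boundary (an intron is
#' split at its midpoint; ties go to the upstream exon), strand-aware.
#'
#' @param tx a [TranscriptModel].
#' @param gpos 1-based genomic position on `tx`'s contig.
#' @return a [CdsCoord].
#' @export
genomicToCdna <- function(tx, gpos) {
  str <- .txStructure(tx)
  gpos <- as.integer(gpos)
  if (gpos < str$locusStart || gpos > str$locusEnd)
    stop(.outOfTranscript("position outside the transcript locus"))
  .coordOfIdx(str, str$idxOfGpos(gpos), tx@cdsStart, tx@cdsEnd)
}

#' Map an HGVS coding coordinate back to the genome
#'
#' Exact inverse of [genomicToCdna()] on all valid coordinates.
#'
#' @param tx a [TranscriptModel].
#' @param coord a [CdsCoord].
#' @return 1-based genomic position.
#' @export
cdnaToGenomic <- function(tx, coord) {
  str <- .txStructure(tx)
  str$gposOfIdx(.idxOfCoord(str, coord, tx@cdsStart, tx@cdsEnd))
}

## Full sequence-aware context: locus bases in transcript order with
## overrides applied, plus derived spliced/CDS/protein sequences.
.txContext <- function(tx, genome) {
  str <- .txStructure(tx)
  if (!tx@contig %in% names(genome))
    stop("contig not in genome: ", tx@contig)
  contigSeq <- genome[[tx@contig]]
  win <- as.character(Biostrings::subseq(contigSeq, str$locusStart,
                                         str$locusEnd))
  if (!str$plus) win <- .revComp(win)
  base <- strsplit(win, "", fixed = TRUE)[[1L]]
  ov <- tx@overrides
  if (nrow(ov)) {
    for (r in seq_len(nrow(ov))) {
      i <- str$idxOfGpos(as.integer(ov$gpos[r]))
      if (i < 1L || i > str$L || str$region[i] <= 0L)
        stop("override position not inside an exon: ", ov$gpos[r])
      base[i] <- toupper(ov$base[r])
    }
  }
  txSeq <- paste(base[str$region > 0L], collapse = "")
  cdsSeq <- substr(txSeq, tx@cdsStart, tx@cdsEnd)
  str$base <- base
  str$txSeq <- txSeq
  str$cdsSeq <- cdsSeq
  str$cdsUtr3Seq <- substr(txSeq, tx@cdsStart, nchar(txSeq))
  str$protSeq <- .translateNt(cdsSeq)
  str$cdsStart <- tx@cdsStart
  str$cdsEnd <- tx@cdsEnd
  str
}

#' Spliced transcript sequence
#'
#' Splices the exons, reverse-complements on the minus strand and applies the
#' transcript's reference overrides, so the transcript base (not the genomic
#' base) appears at override positions.
#'
#' @param tx a [TranscriptModel].
#' @param genome a named [Biostrings::DNAStringSet].
#' @return character nucleotide sequence, 5' to 3'.
#' @export
txSequence <- function(tx, genome) .txContext(tx, genome)$txSeq

#' Coding sequence of a transcript
#'
#' @inheritParams txSequence
#' @return character CDS nucleotide sequence (starts ATG, ends at a stop in
#'   well-formed fixtures).
#' @export
cdsSequence <- function(tx, genome) .txContext(tx, genome)$cdsSeq
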