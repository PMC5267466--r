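#' @import methods
#' @importFrom S4Vectors isSingleString
NULL

## ---------------------------------------------------------------------------
## CdsCoord: an HGVS-style coding-DNA coordinate
## ---------------------------------------------------------------------------

#' Coding-DNA coordinate
#'
#' A single HGVS c.-style position: a nonzero coding anchor (negative numbers
#' count into the 5' UTR, star positions into the 3' UTR) plus a signed
#' intron offset (0 for exonic bases, +n downstream of a donor, -n upstream
#' of an acceptor).
#'
#' @slot anchor integer, nonzero coding-base number (for star coordinates the
#'   1-based distance past the stop codon).
#' @slot star logical, `TRUE` for 3' UTR (`*`) anchors.
#' @slot offset integer intron offset; 0 for exonic positions.
#' @export
setClass("CdsCoord",
  representation(anchor = "integer", star = "logical", offset = "integer"),
  prototype(anchor = 1L, star = FALSE, offset = 0L))

setValidity("CdsCoord", function(object) {
  if (length(object@anchor) != 1L || length(object@star) != 1L ||
      length(object@offset) != 1L)
    return("anchor, star and offset must be scalars")
  if (is.na(object@anchor) || object@anchor == 0L)
    return("anchor must be a nonzero integer")
  if (object@star && object@anchor < 0L)
    return("star anchors are positive distances past the stop codon")
  TRUE
})

#' @param anchor,offset,star see slots.
#' @rdname CdsCoord-class
#' @export
CdsCoord <- function(anchor, offset = 0L, star = FALSE) {
  new("CdsCoord", anchor = as.integer(anchor), offset = as.integer(offset),
      star = isTRUE(star))
}

setMethod("show", "CdsCoord", function(object) {
  cat("CdsCoord: ", formatCdsCoord(object), "\n", sep = "")
})

## ---------------------------------------------------------------------------
## TranscriptModel
## ---------------------------------------------------------------------------

#' Transcript model over a fixture genome
#'
#' Exon structure, CDS span and strand of one transcript, plus per-base
#' transcript-versus-genome reference overrides (positions where the curated
#' transcript sequence differs from the underlying assembly, so that a
#' "variant" matching the transcript base is an identity at transcript
#' level).
#'
#' @slot accession transcript accession (synthetic namespace, e.g. TX000001).
#' @slot version positive integer version; `accession.version` is the unique
#'   identifier used by the transcript gate.
#' @slot gene gene symbol.
#' @slot contig contig name on the fixture genome.
#' @slot strand `"+"` or `"-"`.
#' @slot exons [IRanges::IRanges] of genomic exon intervals, ascending.
#' @slot cdsStart,cdsEnd 1-based transcript-coordinate offsets of the CDS.
#' @slot overrides data.frame with columns `gpos` (genomic position) and
#'   `base` (the transcript-strand base carried by the transcript there).
#' @export
setClass("TranscriptModel",
  representation(accession = "character", version = "integer",
                 gene = "character", contig = "character",
                 strand = "character", exons = "IRanges",
                 cdsStart = "integer", cdsEnd = "integer",
                 overrides = "data.frame"))

setValidity("TranscriptModel", function(object) {
  ex <- object@exons
  if (length(ex) == 0L) return("at least one exon is required")
  st <- IRanges::start(ex); en <- IRanges::end(ex)
  if (is.unsorted(st, strictly = TRUE)) return("exons must be ascending")
  if (length(ex) > 1L && any(st[-1L] <= en[-length(ex)]))
    return("exons must not overlap or touch")
  if (!object@strand %in% c("+", "-")) return("strand must be '+' or '-'")
  txLen <- sum(IRanges::width(ex))
  if (object@cdsStart < 1L || object@cdsEnd > txLen ||
      object@cdsStart > object@cdsEnd)
    return("CDS span must lie within the spliced transcript")
  if (object@version < 1L) return("version must be a positive integer")
  ov <- object@overrides
  if (nrow(ov) && (!all(c("gpos", "base") %in% names(ov)) ||
                   anyDuplicated(ov$gpos)))
    return("overrides need unique gpos plus base columns")
  TRUE
})

#' @param accession,version,gene,contig,strand,exons,cdsStart,cdsEnd,overrides
#'   see slots; `exons` may be given as a two-column matrix/data.frame of
#'   start and end.
#' @rdname TranscriptModel-class
#' @export
TranscriptModel <- function(accession, version, gene, contig, strand, exons,
                            cdsStart, cdsEnd,
                            overrides = data.frame(gpos = integer(),
                                                   base = character())) {
  if (!methods::is(exons, "IRanges")) {
    exons <- as.data.frame(exons)
    exons <- IRanges::IRanges(start = as.integer(exons[[1L]]),
                              end = as.integer(exons[[2L]]))
  }
  new("TranscriptModel", accession = as.character(accession),
      version = as.integer(version), gene = as.character(gene),
      contig = as.character(contig), strand = strand,
      exons = exons, cdsStart = as.integer(cdsStart),
      cdsEnd = as.integer(cdsEnd),
      overrides = as.data.frame(overrides))
}

#' @export
setGeneric("txId", function(x) standardGeneric("txId"))

#' Accession.version identifier
#' @param x a `TranscriptModel`.
#' @rdname TranscriptModel-class
#' @export
setMethod("txId", "TranscriptModel", function(x)
  paste0(x@accession, ".", x@version))

setMethod("show", "TranscriptModel", function(object) {
  cat("TranscriptModel ", txId(object), " (", object@gene, ") on ",
      object@contig, object@strand, "\n  ", length(object@exons),
      " exon(s), spliced length ", sum(IRanges::width(object@exons)),
      ", CDS ", object@cdsStart, "..", object@cdsEnd, sep = "")
  if (nrow(object@overrides))
    cat(", ", nrow(object@overrides), " reference override(s)", sep = "")
  cat("\n")
})

## ---------------------------------------------------------------------------
## Changes and expressions
## ---------------------------------------------------------------------------

.codingKinds <- c("substitution", "deletion", "duplication", "insertion",
                  "delins", "identity")

#' Parsed coding-DNA change
#'
#' @slot kind one of substitution, deletion, duplication, insertion, delins,
#'   identity.
#' @slot start,end [CdsCoord] interval endpoints (for insertions the two
#'   flanking positions).
#' @slot refBases,altBases nucleotides when stated (`NA` otherwise).
#' @slot insLength length-only insertion size (e.g. `ins14`), `NA` otherwise;
#'   mutually exclusive with `altBases`.
#' @export
setClass("CodingChange",
  representation(kind = "character", start = "CdsCoord", end = "CdsCoord",
                 refBases = "character", altBases = "character",
                 insLength = "integer"),
  prototype(refBases = NA_character_, altBases = NA_character_,
            insLength = NA_integer_))

setValidity("CodingChange", function(object) {
  if (!object@kind %in% .codingKinds) return("unknown coding change kind")
  if (object@kind == "insertion" && !is.na(object@insLength) &&
      !is.na(object@altBases))
    return("insLength and altBases are mutually exclusive")
  if (object@kind == "identity" && !is.na(object@altBases))
    return("identity carries no alternate bases")
  TRUE
})

.proteinKinds <- c("substitution", "synonymous", "deletion", "duplication",
                   "insertion", "delins", "frameshift", "extension",
                   "identity", "unknown-start")

#' Parsed protein change
#'
#' Residues are stored as three-letter codes (`Ter` for the stop codon).
#'
#' @slot kind one of substitution, synonymous, deletion, duplication,
#'   insertion, delins, frameshift, extension, identity, unknown-start.
#' @slot startRes,endRes residue letters at the interval endpoints (may be
#'   `NA` for bare `p.=`).
#' @slot startPos,endPos residue numbers.
#' @slot altRes character vector of replacement/inserted residues (length 0
#'   when none are stated, as in the frameshift short form).
#' @slot fsNewStop stop distance of a frameshift long form (`NA` unknown).
#' @slot fsLowerBound logical: `TRUE` when the stop distance came from the
#'   `fs*>N` lower-bound dialect.
#' @slot extNewStop distance to the new stop of an extension (`NA` when the
#'   dialect leaves it unknown, as in `ext*?`).
#' @export
setClass("ProteinChange",
  representation(kind = "character", startRes = "character",
                 startPos = "integer", endRes = "character",
                 endPos = "integer", altRes = "character",
                 fsNewStop = "integer", fsLowerBound = "logical",
                 extNewStop = "integer"),
  prototype(startRes = NA_character_, startPos = NA_integer_,
            endRes = NA_character_, endPos = NA_integer_,
            altRes = character(), fsNewStop = NA_integer_,
            fsLowerBound = FALSE, extNewStop = NA_integer_))

setValidity("ProteinChange", function(object) {
  if (!object@kind %in% .proteinKinds) return("unknown protein change kind")
  ok <- c(.aminoAcids3, "Ter")
  res <- c(object@startRes, object@endRes, object@altRes)
  res <- res[!is.na(res)]
  if (length(res) && !all(res %in% ok))
    return("residues must be the 20 amino acids or Ter")
  TRUE
})

#' Parsed HGVS expression
#'
#' @slot accession reference accession (`NA` when the text carried none).
#' @slot version reference version (`NA` when absent).
#' @slot molecule `"c"`, `"g"` or `"p"`.
#' @slot change a [CodingChange] or [ProteinChange].
#' @slot raw the original text.
#' @slot dialectFlags character vector of tolerances applied while parsing
#'   (empty iff the text is already preferred syntax).
#' @export
setClass("HgvsExpression",
  representation(accession = "character", version = "integer",
                 molecule = "character", change = "ANY", raw = "character",
                 dialectFlags = "character"),
  prototype(accession = NA_character_, version = NA_integer_,
            dialectFlags = character()))

setValidity("HgvsExpression", function(object) {
  if (!object@molecule %in% c("c", "g", "p")) return("molecule must be c/g/p")
  if (object@molecule == "p" && !methods::is(object@change, "ProteinChange"))
    return("p. expressions carry a ProteinChange")
  if (object@molecule %in% c("c", "g") &&
      !methods::is(object@change, "CodingChange"))
    return("c./g. expressions carry a CodingChange")
  TRUE
})

setMethod("show", "HgvsExpression", function(object) {
  cat("HgvsExpression: ", formatPreferred(object), sep = "")
  if (length(object@dialectFlags))
    cat("  [", paste(object@dialectFlags, collapse = ", "), "]", sep = "")
  cat("\n  raw: ", object@raw, "\n", sep = "")
})

## ---------------------------------------------------------------------------
## MatchVerdict
## ---------------------------------------------------------------------------

.verdictStatuses <- c("exact", "equivalent", "incorrect", "not_assessed")

#' Outcome of comparing two HGVS expressions
#'
#' @slot status one of exact, equivalent, incorrect, not_assessed.
#' @slot reasons rule tags explaining the verdict (empty only for exact).
#' @export
setClass("MatchVerdict",
  representation(status = "character", reasons = "character"),
  prototype(reasons = character()))

setValidity("MatchVerdict", function(object) {
  if (!object@status %in% .verdictStatuses) return("unknown status")
  if (object@status != "exact" && length(object@reasons) == 0L)
    return("non-exact verdicts must carry at least one reason tag")
  TRUE
})

MatchVerdict <- function(status, reasons = character()) {
  new("MatchVerdict", status = status, reasons = unique(reasons))
}

setMethod("show", "MatchVerdict", function(object) {
  cat("MatchVerdict: ", object@status, sep = "")
  if (length(object@reasons))
    cat(" (", paste(object@reasons, collapse = ", "), ")", sep = "")
  cat("\n")
})

#' Verdict accessors
#' @param x a `MatchVerdict`.
#' @export
setGeneric("verdictStatus", function(x) standardGeneric("verdictStatus"))

#' @rdname verdictStatus
#' @export
setMethod("verdictStatus", "MatchVerdict", function(x) x@status)

#' @rdname verdictStatus
#' @export
setGeneric("verdictReasons", function(x) standardGeneric("verdictReasons"))

#' @rdname verdictStatus
#' @export
setMethod("verdictReasons", "MatchVerdict", function(x) x@reasons)
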