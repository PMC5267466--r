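## Projection of normalized genomic variants onto transcripts: preferred
## coding HGVS, protein consequence, and Sequence Ontology effect terms.

#' Annotation of one variant on one transcript
#'
#' @slot transcript `accession.version` annotated against.
#' @slot coding,protein [HgvsExpression] or `NULL`.
#' @slot effects Sequence Ontology term names (non-empty whenever coding is
#'   present).
#' @slot refDifference `TRUE` when the variant matches a transcript-versus-
#'   genome reference override, in which case `coding` is an identity
#'   expression.
#' @slot status `"annotated"` or `"not_assessed"` (variant outside the
#'   transcript locus).
#' @export
setClass("AnnotationResult",
  representation(transcript = "character", coding = "ANY", protein = "ANY",
                 effects = "character", refDifference = "logical",
                 status = "character"),
  prototype(coding = NULL, protein = NULL, effects = character(),
            refDifference = FALSE, status = "annotated"))

setValidity("AnnotationResult", function(object) {
  if (!object@status %in% c("annotated", "not_assessed"))
    return("status must be annotated or not_assessed")
  if (!is.null(object@coding) && length(object@effects) == 0L)
    return("effects must be non-empty when a coding expression is present")
  if (object@refDifference &&
      (is.null(object@coding) || object@coding@change@kind != "identity"))
    return("refDifference implies an identity coding expression")
  TRUE
})

setMethod("show", "AnnotationResult", function(object) {
  cat("AnnotationResult [", object@status, "] ", object@transcript, "\n",
      sep = "")
  if (!is.null(object@coding))
    cat("  coding:  ", formatPreferred(object@coding), "\n", sep = "")
  if (!is.null(object@protein))
    cat("  protein: ", formatPreferred(object@protein), "\n", sep = "")
  if (length(object@effects))
    cat("  effects: ", paste(object@effects, collapse = ", "), "\n",
        sep = "")
  if (object@refDifference) cat("  transcript-reference difference\n")
})

## Convert one anchored VCF-style record into a transcript-space
## CodingChange (strand-aware, transcript bases from ctx).
.vcfToCodingChange <- function(contig, pos, ref, alt, ctx) {
  tx <- ctx$tx
  if (contig != tx@contig)
    stop(.outOfTranscript("variant on a different contig"))
  nr <- nchar(ref); na <- nchar(alt)
  ## trim the shared anchor base
  if (nr > 1L || na > 1L) {
    if (substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      ref <- substr(ref, 2L, nr); alt <- substr(alt, 2L, na)
      pos <- pos + 1L
      nr <- nr - 1L; na <- na - 1L
    }
  }
  idxOfG <- function(g) {
    if (g < ctx$locusStart || g > ctx$locusEnd)
      stop(.outOfTranscript("position outside the transcript locus"))
    ctx$idxOfGpos(g)
  }
  orient <- function(b) if (ctx$plus) b else .revComp(b)
  coordAt <- function(i) .coordOfIdx(ctx, i, ctx$cdsStart, ctx$cdsEnd)

  if (nr == 1L && na == 1L) {
    i <- idxOfG(pos)
    return(new("CodingChange", kind = "substitution", start = coordAt(i),
               end = coordAt(i), refBases = ctx$base[i],
               altBases = orient(alt)))
  }
  if (nr == 0L) {                               # insertion after pos - 1
    gl <- pos - 1L
    ii <- sort(c(idxOfG(gl), idxOfG(gl + 1L)))
    return(new("CodingChange", kind = "insertion",
               start = coordAt(ii[1L]), end = coordAt(ii[2L]),
               altBases = orient(alt)))
  }
  if (na == 0L) {                               # deletion of ref at pos..
    ii <- sort(c(idxOfG(pos), idxOfG(pos + nr - 1L)))
    s <- ii[1L]; e <- ii[2L]
    return(new("CodingChange", kind = "deletion", start = coordAt(s),
               end = coordAt(e),
               refBases = paste(ctx$base[s:e], collapse = "")))
  }
  ii <- sort(c(idxOfG(pos), idxOfG(pos + nr - 1L)))
  s <- ii[1L]; e <- ii[2L]
  new("CodingChange", kind = "delins", start = coordAt(s),
      end = coordAt(e), refBases = paste(ctx$base[s:e], collapse = ""),
      altBases = orient(alt))
}

.cdsOverlap <- function(ch) {
  pureCds <- function(co) co@offset == 0L && !co@star && co@anchor > 0L
  pureCds(ch@start) && pureCds(ch@end)
}

#' Annotate a genomic variant on a transcript
#'
#' Maps the (left-aligned) variant into transcript coordinates, applies
#' HGVS-side canonicalization (delins reduction, 3'-shifting with the
#' boundary exception, duplication detection), translates the mutated CDS to
#' derive the protein consequence, and classifies Sequence Ontology effects.
#' Variants matching a transcript reference override yield an identity
#' expression with `refDifference = TRUE`; variants outside the transcript
#' locus are reported `not_assessed`.
#'
#' @param variant one-row variant table (or list with contig, pos, ref,
#'   alt).
#' @param tx a [TranscriptModel].
#' @param genome named [Biostrings::DNAStringSet].
#' @param ctx precomputed transcript context (internal; callers annotating
#'   many variants on one transcript reuse it to avoid rebuilding).
#' @return an [AnnotationResult].
#' @export
annotateVariant <- function(variant, tx, genome, ctx = NULL) {
  if (is.null(ctx)) ctx <- .txContext(tx, genome)
  ch <- tryCatch(
    .vcfToCodingChange(variant$contig, as.integer(variant$pos),
                       toupper(variant$ref), toupper(variant$alt), ctx),
    outOfTranscript = function(e) NULL)
  if (is.null(ch))
    return(new("AnnotationResult", transcript = txId(tx),
               status = "not_assessed"))

  refDiff <- FALSE
  if (ch@kind == "substitution" && ch@refBases == ch@altBases) {
    ## VCF alt equals the transcript base: a transcript-genome reference
    ## difference, not a variant at transcript level
    ch <- new("CodingChange", kind = "identity", start = ch@start,
              end = ch@start, refBases = ch@refBases)
    refDiff <- TRUE
  }
  canon <- .shiftCoding(ch, ctx, dir = 3L)
  codingExpr <- new("HgvsExpression", accession = tx@accession,
                    version = tx@version, molecule = "c", change = canon,
                    raw = formatPreferred(new("HgvsExpression",
                                              accession = tx@accession,
                                              version = tx@version,
                                              molecule = "c",
                                              change = canon, raw = "")))

  protein <- NULL
  if (!refDiff && canon@kind != "identity" && .cdsOverlap(canon)) {
    nCodingBases <- ctx$cdsEnd - ctx$cdsStart + 1L
    utr3 <- substr(ctx$txSeq, ctx$cdsEnd + 1L, nchar(ctx$txSeq))
    pch <- translateConsequence(canon, ctx$cdsSeq, utr3)
    protein <- new("HgvsExpression", accession = tx@accession,
                   version = tx@version, molecule = "p", change = pch,
                   raw = "")
    protein@raw <- formatPreferred(protein)
  }
  effects <- .classifyEffectInternal(canon, protein, refDiff)
  new("AnnotationResult", transcript = txId(tx), coding = codingExpr,
      protein = protein, effects = effects, refDifference = refDiff)
}

#' Protein consequence of a CDS-overlapping coding change
#'
#' Translates the edited coding sequence and derives the protein change:
#' frameshifts report the first changed residue, its replacement and the
#' distance to the new stop (long form) unless the first changed residue is
#' itself a stop (a nonsense substitution); stop-loss becomes an extension
#' with the distance to the next in-frame stop in the 3' UTR (unknown when
#' none exists); in-frame insertions equal to the adjacent residues become
#' residue-level duplications; synonymous changes use the `=` form.
#' Protein-level changes are 3'-shifted at residue level (greedy prefix
#' alignment).
#'
#' @param change a [CodingChange] whose coordinates are plain CDS anchors.
#' @param cdsSeq coding nucleotide sequence (length divisible by 3).
#' @param utr3 downstream (3' UTR) nucleotide sequence used for frameshift
#'   and extension stop scanning.
#' @return a [ProteinChange].
#' @export
translateConsequence <- function(change, cdsSeq, utr3 = "") {
  if (nchar(cdsSeq) %% 3L != 0L)
    stop("CDS length must be divisible by 3")
  refNt <- paste0(cdsSeq, utr3)
  ## edit in CDS-anchored linear coordinates
  cpos <- function(co) {
    if (co@offset != 0L || co@star || co@anchor <= 0L)
      stop("change endpoint is not a plain CDS position")
    co@anchor
  }
  a <- cpos(change@start); b <- cpos(change@end)
  varNt <- switch(change@kind,
    substitution = paste0(substr(refNt, 1L, a - 1L), change@altBases,
                          substr(refNt, a + 1L, nchar(refNt))),
    deletion = paste0(substr(refNt, 1L, a - 1L),
                      substr(refNt, b + 1L, nchar(refNt))),
    insertion = paste0(substr(refNt, 1L, a),
                       if (!is.na(change@altBases)) change@altBases
                       else stop("length-only insertion has no sequence"),
                       substr(refNt, a + 1L, nchar(refNt))),
    duplication = paste0(substr(refNt, 1L, b), substr(refNt, a, b),
                         substr(refNt, b + 1L, nchar(refNt))),
    delins = paste0(substr(refNt, 1L, a - 1L), change@altBases,
                    substr(refNt, b + 1L, nchar(refNt))),
    identity = refNt,
    stop("unsupported change kind"))

  refP <- .translateNt(cdsSeq)                  # ends with '*'
  varPfull <- .translateNt(varNt)
  nRef <- nchar(refP)

  if (substr(varPfull, 1L, nRef) == refP && change@kind != "identity") {
    ## protein unchanged: synonymous at the first affected codon
    cod <- (a - 1L) %/% 3L + 1L
    res <- .aaAt(refP, cod)
    return(new("ProteinChange", kind = "synonymous", startRes = res,
               startPos = cod, endRes = res, endPos = cod))
  }
  if (change@kind == "identity")
    return(new("ProteinChange", kind = "identity"))

  n <- min(nRef, nchar(varPfull))
  i <- 1L
  while (i <= n && substr(refP, i, i) == substr(varPfull, i, i)) i <- i + 1L

  refChar <- if (i <= nRef) substr(refP, i, i) else ""
  varChar <- if (i <= nchar(varPfull)) substr(varPfull, i, i) else ""

  if (i == 1L)
    return(new("ProteinChange", kind = "unknown-start", startRes = "Met",
               startPos = 1L, endRes = "Met", endPos = 1L))

  if (varChar == "*")
    return(new("ProteinChange", kind = "substitution",
               startRes = .aa3(refChar), startPos = i,
               endRes = .aa3(refChar), endPos = i, altRes = "Ter"))

  if (refChar == "*") {
    rest <- substr(varPfull, i + 1L, nchar(varPfull))
    stp <- regexpr("*", rest, fixed = TRUE)
    ext <- if (stp > 0L) as.integer(stp) else NA_integer_
    return(new("ProteinChange", kind = "extension", startRes = "Ter",
               startPos = i, endRes = "Ter", endPos = i,
               altRes = .aa3(varChar), extNewStop = ext))
  }

  delta <- nchar(varNt) - nchar(refNt)
  if (delta %% 3L == 0L) {
    ## in-frame: align on the stop, trim common suffix
    refStop <- nRef
    varStop <- regexpr("*", varPfull, fixed = TRUE)
    varStop <- if (varStop > 0L) as.integer(varStop) else nchar(varPfull)
    R <- substr(refP, i, refStop)
    V <- substr(varPfull, i, varStop)
    s <- 0L
    while (s < min(nchar(R), nchar(V)) &&
           substr(R, nchar(R) - s, nchar(R) - s) ==
           substr(V, nchar(V) - s, nchar(V) - s)) s <- s + 1L
    Rrem <- substr(R, 1L, nchar(R) - s)
    Vrem <- substr(V, 1L, nchar(V) - s)
    if (nchar(Rrem) == 0L && nchar(Vrem) > 0L) {
      nV <- nchar(Vrem)
      if (i - 1L >= nV &&
          substr(refP, i - nV, i - 1L) == Vrem) {
        return(new("ProteinChange", kind = "duplication",
                   startRes = .aa3(substr(refP, i - nV, i - nV)),
                   startPos = i - nV,
                   endRes = .aa3(substr(refP, i - 1L, i - 1L)),
                   endPos = i - 1L))
      }
      return(new("ProteinChange", kind = "insertion",
                 startRes = .aa3(substr(refP, i - 1L, i - 1L)),
                 startPos = i - 1L, endRes = .aa3(refChar), endPos = i,
                 altRes = .aa3v(Vrem)))
    }
    if (nchar(Vrem) == 0L)
      return(new("ProteinChange", kind = "deletion",
                 startRes = .aa3(refChar), startPos = i,
                 endRes = .aa3(substr(refP, i + nchar(Rrem) - 1L,
                                      i + nchar(Rrem) - 1L)),
                 endPos = i + nchar(Rrem) - 1L))
    if (nchar(Rrem) == 1L && nchar(Vrem) == 1L)
      return(new("ProteinChange", kind = "substitution",
                 startRes = .aa3(refChar), startPos = i,
                 endRes = .aa3(refChar), endPos = i,
                 altRes = .aa3(Vrem)))
    return(new("ProteinChange", kind = "delins", startRes = .aa3(refChar),
               startPos = i,
               endRes = .aa3(substr(refP, i + nchar(Rrem) - 1L,
                                    i + nchar(Rrem) - 1L)),
               endPos = i + nchar(Rrem) - 1L, altRes = .aa3v(Vrem)))
  }

  ## frameshift: long form with the distance to the new stop when found
  rest <- substr(varPfull, i, nchar(varPfull))
  stp <- regexpr("*", rest, fixed = TRUE)
  fsStop <- if (stp > 0L) as.integer(stp) else NA_integer_
  new("ProteinChange", kind = "frameshift", startRes = .aa3(refChar),
      startPos = i, endRes = .aa3(refChar), endPos = i,
      altRes = if (nzchar(varChar)) .aa3(varChar) else character(),
      fsNewStop = fsStop)
}

.aaAt <- function(p, i) .aa3(substr(p, i, i))
.aa3 <- function(ch) if (ch == "*") "Ter" else unname(.one2three[ch])
.aa3v <- function(s) vapply(strsplit(s, "")[[1L]], .aa3, character(1L),
                            USE.NAMES = FALSE)

.classifyEffectInternal <- function(change, protein, refDiff = FALSE) {
  if (refDiff || change@kind == "identity") return("no_sequence_alteration")
  co <- list(change@start, change@end)
  offs <- vapply(co, function(x) x@offset, integer(1L))
  stars <- vapply(co, function(x) x@star, logical(1L))
  anchors <- vapply(co, function(x) x@anchor, integer(1L))

  spliceTerms <- function(off) {
    t <- character()
    if (off >= 1L && off <= 2L) t <- c(t, "splice_donor_variant")
    if (off <= -1L && off >= -2L) t <- c(t, "splice_acceptor_variant")
    if (abs(off) >= 3L && abs(off) <= 8L) t <- c(t, "splice_region_variant")
    t
  }
  if (all(offs != 0L)) {                 # fully intronic
    terms <- unique(c(unlist(lapply(offs, spliceTerms)), "intron_variant"))
    return(terms)
  }
  if (any(offs != 0L)) {                 # junction-spanning
    terms <- unique(c(unlist(lapply(offs[offs != 0L], spliceTerms)),
                      "intron_variant"))
    if (length(terms) == 1L) terms <- c("splice_region_variant", terms)
    return(terms)
  }
  if (all(stars)) return("3_prime_UTR_variant")
  if (all(anchors < 0L)) return("5_prime_UTR_variant")
  if (any(anchors < 0L) && !any(stars)) return("start_lost")

  if (is.null(protein)) return("coding_sequence_variant")
  pch <- protein@change
  switch(pch@kind,
    substitution = if (length(pch@altRes) && pch@altRes[1L] == "Ter")
                     "stop_gained" else "missense_variant",
    synonymous = if (pch@startRes == "Ter") "stop_retained_variant"
                 else "synonymous_variant",
    frameshift = "frameshift_variant",
    extension = "stop_lost",
    deletion = "inframe_deletion",
    duplication = "inframe_insertion",
    insertion = "inframe_insertion",
    delins = {
      nref <- pch@endPos - pch@startPos + 1L
      nalt <- length(pch@altRes)
      if (nref == nalt) "missense_variant"
      else if (nalt > nref) "inframe_insertion" else "inframe_deletion"
    },
    `unknown-start` = "start_lost",
    identity = "no_sequence_alteration",
    "coding_sequence_variant")
}

#' Sequence Ontology effect terms for a coding change
#'
#' Returns all applicable terms (a deletion at acceptor offset -1 is both a
#' `splice_acceptor_variant` and an `intron_variant`); effect terms co-vary
#' exactly with the protein change kind for CDS variants.
#'
#' @param change a [CodingChange] in transcript coordinates.
#' @param protein the matching [HgvsExpression] protein annotation or
#'   `NULL`.
#' @param refDifference `TRUE` for transcript-reference-difference
#'   identities.
#' @return character vector of SO term names.
#' @export
classifyEffect <- function(change, protein = NULL, refDifference = FALSE) {
  .classifyEffectInternal(change, protein, refDifference)
}
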