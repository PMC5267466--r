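## The exact / equivalent / incorrect / not_assessed classifier for pairs of
## HGVS expressions, gated on transcript accession AND version.
##
## The default comparison is the conservative string-level closure: dialect
## normalization, delins reduction, and the single-base insertion/duplication
## adjacency rule.  Position re-shifting and multi-base ins<->dup merging
## against the reference sequence are applied only when a transcript is
## supplied with verify = TRUE; failure to right-shift therefore classes as
## incorrect, and multi-base insertions are not asserted equivalent to
## duplications without sequence verification.

.asExpression <- function(x) {
  if (methods::is(x, "HgvsExpression")) return(x)
  parseHgvs(as.character(x))
}

.rawBody <- function(expr)
  .splitAccession(gsub("[[:space:]]+", "", expr@raw))$rest

#' Compare two HGVS expressions
#'
#' The query transcript must match the reference transcript: when both sides
#' carry an accession and the accession or version differs, the pair is
#' `not_assessed`.  Byte-identical syntax (accession and whitespace aside)
#' is `exact`; canonical forms that agree after dialect normalization (plus
#' sequence-aware canonicalization when a transcript is supplied with
#' `verify = TRUE`) are `equivalent`; anything else is `incorrect`, with
#' rule tags explaining why.
#'
#' @param query,reference HGVS text or [HgvsExpression] objects.
#' @param tx optional [TranscriptModel] for sequence-aware mode.
#' @param genome genome for sequence-aware mode.
#' @param verify apply position re-shifting and multi-base dup verification
#'   against the transcript sequence (requires `tx` and `genome`).
#' @return a [MatchVerdict].
#' @examples
#' verdictStatus(compareExpressions("p.Gln100*", "p.Gln100Ter"))
#' # "equivalent"
#' @export
compareExpressions <- function(query, reference, tx = NULL, genome = NULL,
                               verify = FALSE) {
  q <- tryCatch(.asExpression(query), hgvsParseError = function(e) e)
  r <- tryCatch(.asExpression(reference), hgvsParseError = function(e) e)
  if (methods::is(q, "condition") || methods::is(r, "condition"))
    return(MatchVerdict("incorrect", "parse-failure"))

  if (!is.na(q@accession) && !is.na(r@accession)) {
    if (q@accession != r@accession)
      return(MatchVerdict("not_assessed", "transcript-accession-mismatch"))
    if (!is.na(q@version) && !is.na(r@version) && q@version != r@version)
      return(MatchVerdict("not_assessed", "transcript-version-mismatch"))
  }
  if (q@molecule != r@molecule) {
    if (xor(q@molecule == "p", r@molecule == "p"))
      return(MatchVerdict("incorrect", "molecule-mismatch"))
  }
  if (identical(.rawBody(q), .rawBody(r)))
    return(MatchVerdict("exact"))

  res <- if (q@molecule == "p")
    .equivProtein(q, r, tx, genome, verify)
  else
    .equivCoding(q, r, tx, genome, verify)

  flags <- unique(c(q@dialectFlags, r@dialectFlags))
  if (res$eq) {
    reasons <- unique(c(res$reasons, flags))
    if (length(reasons) == 0L) reasons <- "dialect-only"
    MatchVerdict("equivalent", reasons)
  } else {
    MatchVerdict("incorrect",
                 if (length(res$reasons)) res$reasons else "not-equivalent")
  }
}

## ---------------------------------------------------------------------------
## coding equivalence
## ---------------------------------------------------------------------------

.canonCoding <- function(ch, tx, genome, verify) {
  out <- reduceDelins(ch, tx, genome)
  if (verify && !is.null(tx) && !is.null(genome))
    out <- tryCatch(shift3Coding(out, tx, genome),
                    outOfTranscript = function(e) out,
                    referenceMismatch = function(e) out)
  out
}

## strict structural equality; returns "equal", "lenonly" or FALSE
.codingStructEqual <- function(a, b) {
  if (a@kind != b@kind) return(FALSE)
  if (!.coordEqual(a@start, b@start) || !.coordEqual(a@end, b@end))
    return(FALSE)
  bothEq <- function(x, y) is.na(x) || is.na(y) || x == y
  if (!bothEq(a@refBases, b@refBases)) return(FALSE)
  if (a@kind == "insertion") {
    aLen <- !is.na(a@insLength); bLen <- !is.na(b@insLength)
    if (!aLen && !bLen) return(if (a@altBases == b@altBases) "equal"
                               else FALSE)
    la <- if (aLen) a@insLength else nchar(a@altBases)
    lb <- if (bLen) b@insLength else nchar(b@altBases)
    if (la != lb) return(FALSE)
    return(if (aLen && bLen) "equal" else "lenonly")
  }
  if (!bothEq(a@altBases, b@altBases)) return(FALSE)
  "equal"
}

.width1 <- function(ch)
  .coordEqual(ch@start, ch@end)

## single-base insertion <-> duplication adjacency (sequence-free): the
## insertion of X immediately before or after position p matches dup at p
## unless a stated duplicated base contradicts X.
.insDupAdjacent <- function(ins, dup) {
  if (ins@kind != "insertion" || dup@kind != "duplication") return(FALSE)
  if (!.width1(dup)) return(FALSE)
  X <- ins@altBases
  if (is.na(X) || nchar(X) != 1L) return(FALSE)
  if (!is.na(dup@refBases) && dup@refBases != X) return(FALSE)
  .coordEqual(ins@start, dup@start) || .coordEqual(ins@end, dup@start)
}

.equivCoding <- function(q, r, tx, genome, verify) {
  a <- .canonCoding(q@change, tx, genome, verify)
  b <- .canonCoding(r@change, tx, genome, verify)
  se <- .codingStructEqual(a, b)
  if (identical(se, "equal")) {
    extra <- character()
    if (q@change@kind != a@kind || r@change@kind != b@kind ||
        !.coordEqual(q@change@start, a@start) ||
        !.coordEqual(r@change@start, b@start))
      extra <- "shift-normalized"
    return(list(eq = TRUE, reasons = extra))
  }
  if (identical(se, "lenonly"))
    return(list(eq = TRUE, reasons = "length-only-insertion"))
  if (.insDupAdjacent(a, b) || .insDupAdjacent(b, a))
    return(list(eq = TRUE, reasons = "dup-vs-ins"))

  ## diagnosis of the mismatch
  reasons <- character()
  kinds <- sort(c(a@kind, b@kind))
  if (a@kind == b@kind) {
    wA <- .coordDiff(a@start, a@end); wB <- .coordDiff(b@start, b@end)
    sameAllele <- switch(a@kind,
      deletion = , duplication = is.na(a@refBases) || is.na(b@refBases) ||
        a@refBases == b@refBases,
      insertion = !is.na(a@altBases) && !is.na(b@altBases) &&
        a@altBases == b@altBases,
      delins = !is.na(a@altBases) && !is.na(b@altBases) &&
        a@altBases == b@altBases,
      FALSE)
    if (!is.na(wA) && !is.na(wB) && wA == wB && isTRUE(sameAllele) &&
        !(.coordEqual(a@start, b@start)))
      reasons <- "shift-difference"
    else if (a@kind == "substitution")
      reasons <- "allele-mismatch"
    else reasons <- "change-mismatch"
  } else if (identical(kinds, c("duplication", "insertion"))) {
    reasons <- "dup-vs-ins"
  } else {
    reasons <- "kind-mismatch"
  }
  list(eq = FALSE, reasons = reasons)
}

## ---------------------------------------------------------------------------
## protein equivalence
## ---------------------------------------------------------------------------

.protResAt <- function(protSeq, i) {
  if (i < 1L || i > nchar(protSeq)) return(NA_character_)
  .aa3(substr(protSeq, i, i))
}

## Residue-level sequence-aware canonicalization: validates stated residues
## against the translated CDS, 3'-shifts insertions/deletions at residue
## level and detects residue-level duplications.
.canonProteinChange <- function(pch, protSeq) {
  at <- function(i) .protResAt(protSeq, i)
  if (!is.na(pch@startPos) && !is.na(pch@startRes)) {
    if (!identical(at(pch@startPos), pch@startRes)) return(pch)
  }
  if (!is.na(pch@endPos) && !is.na(pch@endRes) &&
      !identical(at(pch@endPos), pch@endRes)) return(pch)
  n <- nchar(protSeq)

  if (pch@kind == "duplication") {
    ## re-route through the insertion shifter
    unit <- vapply(pch@startPos:pch@endPos, at, character(1L))
    return(.shiftProteinIns(protSeq, p = pch@endPos, I = unit))
  }
  if (pch@kind == "insertion")
    return(.shiftProteinIns(protSeq, p = pch@startPos, I = pch@altRes))
  if (pch@kind == "deletion") {
    s <- pch@startPos; e <- pch@endPos
    while (e + 1L <= n && at(s) == at(e + 1L)) { s <- s + 1L; e <- e + 1L }
    return(new("ProteinChange", kind = "deletion", startRes = at(s),
               startPos = s, endRes = at(e), endPos = e))
  }
  if (pch@kind == "delins") {
    ref <- vapply(pch@startPos:pch@endPos, at, character(1L))
    alt <- pch@altRes
    p <- 0L
    while (p < min(length(ref), length(alt)) && ref[p + 1L] == alt[p + 1L])
      p <- p + 1L
    s <- 0L
    while (s < min(length(ref) - p, length(alt) - p) &&
           ref[length(ref) - s] == alt[length(alt) - s]) s <- s + 1L
    ref2 <- ref[seq_len(length(ref) - s)][-seq_len(p)]
    alt2 <- alt[seq_len(length(alt) - s)][-seq_len(p)]
    s1 <- pch@startPos + p; e1 <- pch@endPos - s
    if (length(ref2) == 0L && length(alt2) > 0L)
      return(.shiftProteinIns(protSeq, p = s1 - 1L, I = alt2))
    if (length(alt2) == 0L && length(ref2) > 0L)
      return(.canonProteinChange(
        new("ProteinChange", kind = "deletion", startRes = at(s1),
            startPos = s1, endRes = at(e1), endPos = e1), protSeq))
    if (length(ref2) == 1L && length(alt2) == 1L)
      return(new("ProteinChange",
                 kind = if (alt2 == ref2) "synonymous" else "substitution",
                 startRes = at(s1), startPos = s1, endRes = at(s1),
                 endPos = s1, altRes = if (alt2 == ref2) character()
                                       else alt2))
    if (length(ref2) == 0L && length(alt2) == 0L)
      return(new("ProteinChange", kind = "synonymous", startRes = at(s1),
                 startPos = s1, endRes = at(s1), endPos = s1))
    return(new("ProteinChange", kind = "delins", startRes = at(s1),
               startPos = s1, endRes = at(e1), endPos = e1,
               altRes = alt2))
  }
  pch
}

.shiftProteinIns <- function(protSeq, p, I) {
  at <- function(i) .protResAt(protSeq, i)
  n <- length(I)
  len <- nchar(protSeq)
  while (p + 1L <= len && identical(at(p + 1L), I[1L])) {
    I <- c(I[-1L], I[1L])
    p <- p + 1L
  }
  if (p >= n && identical(vapply((p - n + 1L):p, at, character(1L)), I))
    return(new("ProteinChange", kind = "duplication",
               startRes = at(p - n + 1L), startPos = p - n + 1L,
               endRes = at(p), endPos = p))
  new("ProteinChange", kind = "insertion", startRes = at(p), startPos = p,
      endRes = at(p + 1L), endPos = p + 1L, altRes = I)
}

.equivProtein <- function(q, r, tx, genome, verify) {
  a <- q@change; b <- r@change
  if (verify && !is.null(tx) && !is.null(genome)) {
    protSeq <- .txContext(tx, genome)$protSeq
    a <- .canonProteinChange(a, protSeq)
    b <- .canonProteinChange(b, protSeq)
  }

  ## bare p.= matches any synonymous description
  if (a@kind == "identity" || b@kind == "identity") {
    other <- if (a@kind == "identity") b else a
    if (other@kind %in% c("identity", "synonymous"))
      return(list(eq = TRUE, reasons = "dialect-only"))
    return(list(eq = FALSE, reasons = "synonymous-mismatch"))
  }

  ## frameshift ending immediately in a stop == nonsense substitution
  fsTer1 <- function(x, y)
    x@kind == "frameshift" && identical(x@fsNewStop, 1L) &&
      !x@fsLowerBound && y@kind == "substitution" &&
      length(y@altRes) == 1L && y@altRes == "Ter" &&
      x@startPos == y@startPos && x@startRes == y@startRes
  if (fsTer1(a, b) || fsTer1(b, a))
    return(list(eq = TRUE, reasons = "fs-ter1"))

  if (a@kind == "frameshift" && b@kind == "frameshift") {
    if (a@startPos != b@startPos || a@startRes != b@startRes)
      return(list(eq = FALSE, reasons = "shift-difference"))
    if (length(a@altRes) && length(b@altRes) && a@altRes != b@altRes)
      return(list(eq = FALSE, reasons = "fs-form"))
    if (!is.na(a@fsNewStop) && !is.na(b@fsNewStop) &&
        a@fsNewStop != b@fsNewStop)
      return(list(eq = FALSE, reasons = "fs-form"))
    tags <- if (length(a@altRes) != length(b@altRes) ||
                is.na(a@fsNewStop) != is.na(b@fsNewStop) ||
                a@fsLowerBound != b@fsLowerBound) "fs-form" else character()
    return(list(eq = TRUE, reasons = tags))
  }
  if (a@kind != b@kind) {
    kinds <- sort(c(a@kind, b@kind))
    if (identical(kinds, c("duplication", "insertion")))
      return(list(eq = FALSE, reasons = "dup-vs-ins"))
    return(list(eq = FALSE, reasons = "kind-mismatch"))
  }

  same <- function(...) {
    vals <- list(...)
    all(vapply(vals, isTRUE, logical(1L)))
  }
  posEq <- same(a@startPos == b@startPos, a@endPos == b@endPos,
                a@startRes == b@startRes, a@endRes == b@endRes)
  switch(a@kind,
    synonymous = if (posEq) list(eq = TRUE, reasons = character())
                 else list(eq = FALSE, reasons = "position-mismatch"),
    substitution = if (posEq && identical(a@altRes, b@altRes))
                     list(eq = TRUE, reasons = character())
                   else list(eq = FALSE, reasons = "allele-mismatch"),
    extension = {
      if (!posEq || !identical(a@altRes, b@altRes))
        return(list(eq = FALSE, reasons = "allele-mismatch"))
      if (!is.na(a@extNewStop) && !is.na(b@extNewStop) &&
          a@extNewStop != b@extNewStop)
        return(list(eq = FALSE, reasons = "ext-form"))
      tags <- if (is.na(a@extNewStop) != is.na(b@extNewStop)) "ext-form"
              else character()
      list(eq = TRUE, reasons = tags)
    },
    deletion = ,
    duplication = if (posEq) list(eq = TRUE, reasons = character())
                  else list(eq = FALSE, reasons = "shift-difference"),
    insertion = ,
    delins = {
      if (posEq && identical(a@altRes, b@altRes))
        list(eq = TRUE, reasons = character())
      else if (identical(a@altRes, b@altRes))
        list(eq = FALSE, reasons = "shift-difference")
      else list(eq = FALSE, reasons = "allele-mismatch")
    },
    `unknown-start` = list(eq = TRUE, reasons = character()),
    list(eq = FALSE, reasons = "kind-mismatch"))
}

## ---------------------------------------------------------------------------
## canonical keys
## ---------------------------------------------------------------------------

#' Canonical comparison key for an HGVS expression
#'
#' Deterministic normal form: dialect normalization plus delins reduction,
#' and - when a transcript is supplied - sequence-aware canonicalization
#' (3'-shifting, duplication detection, residue validation; synonymous
#' protein changes collapse to `p.=` because the residue context is known).
#' Equal keys imply equivalence under the corresponding mode; the comparator
#' additionally applies rule-tagged closures (fs forms, length-only
#' insertions, single-base ins/dup adjacency) that a single string cannot
#' encode.
#'
#' @param expr HGVS text or an [HgvsExpression].
#' @param tx,genome optional transcript context.
#' @return character key.
#' @export
canonicalKey <- function(expr, tx = NULL, genome = NULL) {
  e <- .asExpression(expr)
  seqAware <- !is.null(tx) && !is.null(genome)
  if (e@molecule == "p") {
    pch <- e@change
    if (seqAware) {
      protSeq <- .txContext(tx, genome)$protSeq
      pch <- .canonProteinChange(pch, protSeq)
      if (pch@kind == "synonymous")
        return("p.=")
    }
    return(paste0("p.", .formatProteinChange(pch)))
  }
  ch <- reduceDelins(e@change, tx, genome)
  if (seqAware) {
    ch <- tryCatch(shift3Coding(ch, tx, genome),
                   outOfTranscript = function(err) ch,
                   referenceMismatch = function(err) ch)
    if (ch@kind %in% c("substitution", "identity") && !is.na(ch@refBases)) {
      ## keep the stated reference base: asserting the wrong base is an
      ## error, not a dialect
    } else if (ch@kind %in% c("substitution", "identity")) {
      ctx <- .txContext(tx, genome)
      i <- tryCatch(.idxOfCoord(ctx, ch@start, ctx$cdsStart, ctx$cdsEnd),
                    outOfTranscript = function(err) NA_integer_)
      if (!is.na(i)) ch@refBases <- ctx$base[i]
    }
  }
  paste0(e@molecule, ".", .formatCodingChange(ch, keepDelBases = FALSE))
}
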