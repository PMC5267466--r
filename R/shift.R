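## HGVS-side sequence-aware canonicalization: 3'-shifting with the
## intron-exon boundary exception, duplication detection, and
## deletion-insertion reduction.
##
## Shifting runs in transcript-direction locus-index space (see coords.R).
## The boundary exception applies in both directions: a fully intronic
## change never shifts into an exon and a fully exonic change never shifts
## into an intron; shifting that merely approaches the border is required.

#' Reduce a deletion-insertion to its minimal form
#'
#' Strips bases shared between the deleted and inserted sequences (greedy
#' prefix first, then suffix, which also minimizes the deleted-base count),
#' then reclassifies: an empty deletion side becomes an insertion, a
#' single-base residue a substitution, identical alleles an identity;
#' anything else stays a minimal delins.
#'
#' @param change a [CodingChange]; non-delins changes pass through.
#' @param tx,genome optional transcript context used to fill in unstated
#'   deleted bases.
#' @return a [CodingChange].
#' @examples
#' ch <- parseCoding("c.1960delCinsCG")@change
#' reduceDelins(ch)   # insertion of G between 1960 and 1961
#' @export
reduceDelins <- function(change, tx = NULL, genome = NULL) {
  if (change@kind != "delins") return(change)
  D <- change@refBases
  if (is.na(D) && !is.null(tx) && !is.null(genome)) {
    ctx <- .txContext(tx, genome)
    s <- .idxOfCoord(ctx, change@start, ctx$cdsStart, ctx$cdsEnd)
    e <- .idxOfCoord(ctx, change@end, ctx$cdsStart, ctx$cdsEnd)
    D <- paste(ctx$base[s:e], collapse = "")
  }
  I <- change@altBases
  if (is.na(D) || is.na(I)) return(change)
  nD <- nchar(D); nI <- nchar(I)
  p <- 0L
  while (p < min(nD, nI) &&
         substr(D, p + 1L, p + 1L) == substr(I, p + 1L, p + 1L)) p <- p + 1L
  s <- 0L
  while (s < min(nD - p, nI - p) &&
         substr(D, nD - s, nD - s) == substr(I, nI - s, nI - s)) s <- s + 1L
  D2 <- substr(D, p + 1L, nD - s)
  I2 <- substr(I, p + 1L, nI - s)
  start2 <- .coordAdd(change@start, p)
  end2 <- .coordAdd(change@end, -s)
  if (nchar(D2) == 0L && nchar(I2) == 0L)
    return(new("CodingChange", kind = "identity", start = change@start,
               end = change@start, refBases = substr(D, 1L, 1L)))
  if (nchar(D2) == 0L) {
    ## pure insertion between the last kept 5' base and the next base
    a <- .coordAdd(change@start, p - 1L)
    b <- .coordAdd(change@start, p)
    return(new("CodingChange", kind = "insertion", start = a, end = b,
               altBases = I2))
  }
  if (nchar(I2) == 0L)
    return(new("CodingChange", kind = "deletion", start = start2,
               end = end2, refBases = D2))
  if (nchar(D2) == 1L && nchar(I2) == 1L)
    return(new("CodingChange", kind = "substitution", start = start2,
               end = start2, refBases = D2, altBases = I2))
  new("CodingChange", kind = "delins", start = start2, end = end2,
      refBases = D2, altBases = I2)
}

## Contiguous same-region run [first,last] containing locus index i.
.regionRun <- function(ctx, i) {
  r <- ctx$region[i]
  first <- i
  while (first > 1L && ctx$region[first - 1L] == r) first <- first - 1L
  last <- i
  while (last < ctx$L && ctx$region[last + 1L] == r) last <- last + 1L
  list(r = r, first = first, last = last)
}

.codingIntervalFromIdx <- function(ctx, s, e) {
  list(start = .coordOfIdx(ctx, s, ctx$cdsStart, ctx$cdsEnd),
       end = .coordOfIdx(ctx, e, ctx$cdsStart, ctx$cdsEnd))
}

#' 3'-shift a coding change against its transcript
#'
#' Deletions, insertions, duplications and reducible delins are moved to
#' their right-most (most 3') representation within their repeat context,
#' never crossing an intron-exon boundary in either direction.  Insertions
#' whose bases equal the immediately 5'-adjacent reference become
#' duplications.  Idempotent.
#'
#' @param change a [CodingChange].
#' @param tx a [TranscriptModel].
#' @param genome named [Biostrings::DNAStringSet].
#' @return the canonical [CodingChange].
#' @export
shift3Coding <- function(change, tx, genome) {
  ctx <- .txContext(tx, genome)
  .shiftCoding(change, ctx, dir = 3L)
}

.shiftCoding <- function(change, ctx, dir = 3L) {
  kind <- change@kind
  if (kind %in% c("substitution", "identity")) return(change)
  if (kind == "delins") {
    red <- reduceDelins(change, NULL, NULL)
    if (is.na(change@refBases)) {
      ## fill deleted bases from sequence, then reduce
      s <- .idxOfCoord(ctx, change@start, ctx$cdsStart, ctx$cdsEnd)
      e <- .idxOfCoord(ctx, change@end, ctx$cdsStart, ctx$cdsEnd)
      filled <- new("CodingChange", kind = "delins", start = change@start,
                    end = change@end,
                    refBases = paste(ctx$base[s:e], collapse = ""),
                    altBases = change@altBases)
      red <- reduceDelins(filled, NULL, NULL)
    }
    if (red@kind == "delins") return(red)
    return(.shiftCoding(red, ctx, dir))
  }

  if (kind == "deletion") {
    s <- .idxOfCoord(ctx, change@start, ctx$cdsStart, ctx$cdsEnd)
    e <- .idxOfCoord(ctx, change@end, ctx$cdsStart, ctx$cdsEnd)
    if (length(unique(ctx$region[s:e])) != 1L) return(change)  # junction-spanning
    run <- .regionRun(ctx, s)
    if (dir == 3L) {
      while (e + 1L <= run$last && ctx$base[s] == ctx$base[e + 1L]) {
        s <- s + 1L; e <- e + 1L
      }
    } else {
      while (s - 1L >= run$first && ctx$base[e] == ctx$base[s - 1L]) {
        s <- s - 1L; e <- e - 1L
      }
    }
    iv <- .codingIntervalFromIdx(ctx, s, e)
    return(new("CodingChange", kind = "deletion", start = iv$start,
               end = iv$end,
               refBases = paste(ctx$base[s:e], collapse = "")))
  }

  if (kind == "duplication") {
    s <- .idxOfCoord(ctx, change@start, ctx$cdsStart, ctx$cdsEnd)
    e <- .idxOfCoord(ctx, change@end, ctx$cdsStart, ctx$cdsEnd)
    if (length(unique(ctx$region[s:e])) != 1L) return(change)
    I <- paste(ctx$base[s:e], collapse = "")
    if (!is.na(change@refBases) && change@refBases != I)
      stop(.refMismatch("duplicated bases disagree with the reference"))
    return(.shiftInsertion(ctx, p = e, I = I, dir = dir))
  }

  if (kind == "insertion") {
    if (is.na(change@altBases)) return(change)  # length-only: cannot shift
    p <- .idxOfCoord(ctx, change@start, ctx$cdsStart, ctx$cdsEnd)
    q <- .idxOfCoord(ctx, change@end, ctx$cdsStart, ctx$cdsEnd)
    if (q != p + 1L || ctx$region[p] != ctx$region[q])
      return(change)  # insertion at a region boundary: leave as written
    return(.shiftInsertion(ctx, p = p, I = change@altBases, dir = dir))
  }
  change
}

## Shift an insertion sitting after locus index p within its region run;
## emit a duplication when the inserted bases copy the immediately
## 5'-adjacent accession sequence.
.shiftInsertion <- function(ctx, p, I, dir = 3L) {
  n <- nchar(I)
  run <- .regionRun(ctx, p)
  if (dir == 3L) {
    while (p + 1L <= run$last && ctx$base[p + 1L] == substr(I, 1L, 1L)) {
      I <- paste0(substr(I, 2L, n), substr(I, 1L, 1L))
      p <- p + 1L
    }
  } else {
    while (p - 1L >= run$first && p >= run$first &&
           ctx$base[p] == substr(I, n, n)) {
      I <- paste0(substr(I, n, n), substr(I, 1L, n - 1L))
      p <- p - 1L
    }
  }
  ## duplication check against the accession sequence: for exonic context
  ## adjacency is on the spliced transcript (the preceding coding bases may
  ## live in the previous exon); for intronic context it is intron-local.
  dup <- FALSE
  dupIdx <- NULL
  if (dir == 3L) {
    if (ctx$region[p] > 0L) {
      tp <- ctx$tpos[p]
      if (!is.na(tp) && tp >= n) {
        idx <- ctx$idxByTpos[(tp - n + 1L):tp]
        if (paste(ctx$base[idx], collapse = "") == I) {
          dup <- TRUE; dupIdx <- idx
        }
      }
    } else if (p - n + 1L >= run$first) {
      idx <- (p - n + 1L):p
      if (paste(ctx$base[idx], collapse = "") == I) {
        dup <- TRUE; dupIdx <- idx
      }
    }
  }
  if (dup) {
    iv <- .codingIntervalFromIdx(ctx, dupIdx[1L], dupIdx[length(dupIdx)])
    return(new("CodingChange", kind = "duplication", start = iv$start,
               end = iv$end, refBases = I))
  }
  if (p + 1L > ctx$L)
    stop(.outOfTranscript("insertion shifted past the transcript locus"))
  iv <- .codingIntervalFromIdx(ctx, p, p + 1L)
  new("CodingChange", kind = "insertion", start = iv$start, end = iv$end,
      altBases = I)
}

## 5'-most (left-most within the region) representation; used by the
## synthetic corruption modes to fabricate failure-to-right-shift records.
.shift5Coding <- function(change, tx, genome) {
  ctx <- .txContext(tx, genome)
  out <- .shiftCoding(change, ctx, dir = 5L)
  if (out@kind == "duplication") {
    ## present as an unshifted form, not a dup
    s <- .idxOfCoord(ctx, out@start, ctx$cdsStart, ctx$cdsEnd)
    e <- .idxOfCoord(ctx, out@end, ctx$cdsStart, ctx$cdsEnd)
    I <- paste(ctx$base[s:e], collapse = "")
    return(.shiftCoding(new("CodingChange", kind = "insertion",
                            start = .coordOfIdx(ctx, s - 1L, ctx$cdsStart,
                                                ctx$cdsEnd),
                            end = .coordOfIdx(ctx, s, ctx$cdsStart,
                                              ctx$cdsEnd),
                            altBases = I),
                       ctx, dir = 5L))
  }
  out
}

#' Apply a coding change to the spliced transcript sequence
#'
#' The sequence-application oracle: edits the transcript sequence (overrides
#' applied) according to the change.  Endpoints must be exonic.
#'
#' @inheritParams shift3Coding
#' @return edited spliced transcript sequence (character).
#' @export
applyCodingChange <- function(change, tx, genome) {
  ctx <- .txContext(tx, genome)
  .applyChangeTx(change, ctx)
}

.applyChangeTx <- function(change, ctx) {
  tposOf <- function(coord) {
    i <- .idxOfCoord(ctx, coord, ctx$cdsStart, ctx$cdsEnd)
    if (ctx$region[i] <= 0L)
      stop(.outOfTranscript("change endpoint is intronic"))
    ctx$tpos[i]
  }
  s <- ctx$txSeq
  switch(change@kind,
    identity = s,
    substitution = {
      tp <- tposOf(change@start)
      paste0(substr(s, 1L, tp - 1L), change@altBases,
             substr(s, tp + 1L, nchar(s)))
    },
    deletion = {
      a <- tposOf(change@start); b <- tposOf(change@end)
      paste0(substr(s, 1L, a - 1L), substr(s, b + 1L, nchar(s)))
    },
    insertion = {
      a <- tposOf(change@start)
      ins <- if (!is.na(change@altBases)) change@altBases
             else strrep("N", change@insLength)
      paste0(substr(s, 1L, a), ins, substr(s, a + 1L, nchar(s)))
    },
    duplication = {
      a <- tposOf(change@start); b <- tposOf(change@end)
      paste0(substr(s, 1L, b), substr(s, a, b), substr(s, b + 1L, nchar(s)))
    },
    delins = {
      a <- tposOf(change@start); b <- tposOf(change@end)
      paste0(substr(s, 1L, a - 1L), change@altBases,
             substr(s, b + 1L, nchar(s)))
    },
    stop("unknown coding change kind"))
}

## Apply a change in locus space (introns included); used by oracles that
## compare whole-locus edited sequences.
.applyChangeLocus <- function(change, ctx) {
  idxOf <- function(coord) .idxOfCoord(ctx, coord, ctx$cdsStart, ctx$cdsEnd)
  b <- ctx$base
  switch(change@kind,
    identity = paste(b, collapse = ""),
    substitution = {
      i <- idxOf(change@start); b[i] <- change@altBases
      paste(b, collapse = "")
    },
    deletion = {
      s <- idxOf(change@start); e <- idxOf(change@end)
      paste(b[-(s:e)], collapse = "")
    },
    insertion = {
      p <- idxOf(change@start)
      paste0(paste(b[1:p], collapse = ""), change@altBases,
             paste(b[(p + 1L):length(b)], collapse = ""))
    },
    duplication = {
      s <- idxOf(change@start); e <- idxOf(change@end)
      paste0(paste(b[1:e], collapse = ""),
             paste(b[s:e], collapse = ""),
             paste(b[(e + 1L):length(b)], collapse = ""))
    },
    delins = {
      s <- idxOf(change@start); e <- idxOf(change@end)
      paste0(paste(b[1:(s - 1L)], collapse = ""), change@altBases,
             paste(b[(e + 1L):length(b)], collapse = ""))
    },
    stop("unknown coding change kind"))
}
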