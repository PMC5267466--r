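## Dialect-tolerant parsing of coding (c./g.) and protein (p.) HGVS.
##
## The parser accepts the preferred 2016 syntax plus the non-compliant
## dialects found in the wild: embedded whitespace ("c.1895 + 5"), one-letter
## amino acids, "*"/"X" for Ter, substitution-style indels
## ("c.3141_3142GA>TT"), omitted "del" designators ("c.2199-1301GA>A"),
## length-only insertions ("ins14"), fs short forms and "fs*>N" lower
## bounds.  Every tolerance used is recorded as a dialect flag; gibberish is
## rejected with a classed condition rather than guessed at.

.hgvsParseError <- function(text, why) {
  stop(structure(class = c("hgvsParseError", "error", "condition"),
                 list(message = paste0("cannot parse HGVS '", text, "': ",
                                       why),
                      call = NULL)))
}

.posPat <- "\\*?-?\\d+(?:[+-]\\d+)?"

.parseCdsPos <- function(s) {
  m <- regmatches(s, regexec("^(\\*)?(-?\\d+)(?:([+-])(\\d+))?$", s))[[1L]]
  if (length(m) == 0L) return(NULL)
  star <- m[2L] == "*"
  anchor <- as.integer(m[3L])
  if (is.na(anchor) || anchor == 0L) return(NULL)
  offset <- if (m[4L] == "") 0L else
    as.integer(m[5L]) * (if (m[4L] == "+") 1L else -1L)
  CdsCoord(anchor, offset, star)
}

## Advance a coordinate by k bases along the same regime (exon run, intron
## run or 3' UTR), skipping the nonexistent coding base 0.
.coordAdd <- function(coord, k) {
  k <- as.integer(k)
  if (coord@offset != 0L)
    return(new("CdsCoord", anchor = coord@anchor, star = coord@star,
               offset = coord@offset + k))
  a <- coord@anchor + k
  if (!coord@star && coord@anchor < 0L && a >= 0L) a <- a + 1L
  if (!coord@star && coord@anchor > 0L && a <= 0L) a <- a - 1L
  new("CdsCoord", anchor = a, star = coord@star, offset = 0L)
}

## Signed distance b - a when the two coordinates live on one linear regime;
## NA otherwise (used only for sanity checks, never for mapping).
.coordDiff <- function(a, b) {
  if (a@offset != 0L || b@offset != 0L) {
    if (a@anchor == b@anchor && a@star == b@star &&
        sign(a@offset) == sign(b@offset))
      return(b@offset - a@offset)
    return(NA_integer_)
  }
  if (a@star != b@star) return(NA_integer_)
  d <- b@anchor - a@anchor
  if (!a@star && sign(a@anchor) != sign(b@anchor))
    d <- d - sign(d)  # no coding base 0
  d
}

.coordEqual <- function(a, b)
  a@anchor == b@anchor && a@star == b@star && a@offset == b@offset

.splitAccession <- function(text) {
  m <- regmatches(text,
    regexec("^([A-Za-z][A-Za-z0-9_-]*?)(?:\\.([0-9]+))?:(.*)$", text))[[1L]]
  if (length(m)) {
    list(accession = m[2L],
         version = if (m[3L] == "") NA_integer_ else as.integer(m[3L]),
         rest = m[4L])
  } else {
    list(accession = NA_character_, version = NA_integer_, rest = text)
  }
}

.cleanHgvs <- function(text) {
  flags <- character()
  s <- gsub("[[:space:]]+", "", text)
  if (!identical(s, trimws(text))) flags <- c(flags, "whitespace")
  list(s = s, flags = flags)
}

#' Parse a coding (c.) or genomic (g.) HGVS expression
#'
#' @param text HGVS text, optionally prefixed by `accession.version:`.
#' @return an [HgvsExpression] carrying a [CodingChange]; unparseable text
#'   raises a condition of class `hgvsParseError`.
#' @examples
#' parseCoding("NM_000277.1:c.1200-1delG")
#' parseCoding("c.3141_3142GA>TT")   # substitution-style indel dialect
#' parseCoding("c.2262_2263ins14")   # length-only insertion
#' @export
parseCoding <- function(text) {
  cl <- .cleanHgvs(text)
  acc <- .splitAccession(cl$s)
  s <- acc$rest
  m <- regmatches(s, regexec("^([cg])\\.(.+)$", s))[[1L]]
  if (length(m) == 0L) .hgvsParseError(text, "expected c. or g. prefix")
  molecule <- m[2L]
  body <- m[3L]
  flags <- cl$flags
  ## case-normalize base letters without touching the del/dup/ins keywords
  tmp <- gsub("delins", "\001", body, fixed = TRUE)
  tmp <- gsub("del", "\002", tmp, fixed = TRUE)
  tmp <- gsub("dup", "\003", tmp, fixed = TRUE)
  tmp <- gsub("ins", "\004", tmp, fixed = TRUE)
  if (grepl("[acgtn]", tmp)) {
    tmp <- toupper(tmp)
    flags <- c(flags, "lowercase-bases")
  }
  tmp <- gsub("\001", "delins", tmp, fixed = TRUE)
  tmp <- gsub("\002", "del", tmp, fixed = TRUE)
  tmp <- gsub("\003", "dup", tmp, fixed = TRUE)
  body <- gsub("\004", "ins", tmp, fixed = TRUE)

  p <- .posPat
  take <- function(pat) regmatches(body, regexec(pat, body))[[1L]]
  ch <- NULL

  if (length(m <- take(sprintf("^(%s)([ACGTN]*)=$", p)))) {
    c1 <- .parseCdsPos(m[2L])
    if (is.null(c1)) .hgvsParseError(text, "bad position")
    if (nchar(m[3L]) > 1L) .hgvsParseError(text, "identity spans one base")
    ch <- new("CodingChange", kind = "identity", start = c1, end = c1,
              refBases = if (nzchar(m[3L])) m[3L] else NA_character_)
  } else if (length(m <- take(sprintf("^(%s)([ACGTN])>([ACGTN])$", p)))) {
    c1 <- .parseCdsPos(m[2L])
    if (is.null(c1)) .hgvsParseError(text, "bad position")
    if (m[3L] == m[4L]) .hgvsParseError(text, "substitution with ref == alt")
    ch <- new("CodingChange", kind = "substitution", start = c1, end = c1,
              refBases = m[3L], altBases = m[4L])
  } else if (length(m <- take(sprintf(
      "^(%s)(?:_(%s))?del([ACGTN]*)ins([ACGTN]+)$", p, p)))) {
    iv <- .parseInterval(text, m[2L], m[3L], m[4L])
    ch <- new("CodingChange", kind = "delins", start = iv$start,
              end = iv$end,
              refBases = if (nzchar(m[4L])) m[4L] else NA_character_,
              altBases = m[5L])
    if (nzchar(m[4L])) flags <- c(flags, "restated-bases")
  } else if (length(m <- take(sprintf("^(%s)(?:_(%s))?del([ACGTN]*)$",
                                      p, p)))) {
    iv <- .parseInterval(text, m[2L], m[3L], m[4L])
    ch <- new("CodingChange", kind = "deletion", start = iv$start,
              end = iv$end,
              refBases = if (nzchar(m[4L])) m[4L] else NA_character_)
  } else if (length(m <- take(sprintf("^(%s)(?:_(%s))?dup([ACGTN]*)$",
                                      p, p)))) {
    iv <- .parseInterval(text, m[2L], m[3L], m[4L])
    ch <- new("CodingChange", kind = "duplication", start = iv$start,
              end = iv$end,
              refBases = if (nzchar(m[4L])) m[4L] else NA_character_)
    if (nzchar(m[4L])) flags <- c(flags, "restated-bases")
  } else if (length(m <- take(sprintf("^(%s)_(%s)ins([ACGTN]+)$", p, p)))) {
    c1 <- .parseCdsPos(m[2L]); c2 <- .parseCdsPos(m[3L])
    if (is.null(c1) || is.null(c2)) .hgvsParseError(text, "bad position")
    d <- .coordDiff(c1, c2)
    if (!is.na(d) && d != 1L)
      .hgvsParseError(text, "insertion interval must span adjacent bases")
    ch <- new("CodingChange", kind = "insertion", start = c1, end = c2,
              altBases = m[4L])
  } else if (length(m <- take(sprintf("^(%s)_(%s)ins([0-9]+)$", p, p)))) {
    c1 <- .parseCdsPos(m[2L]); c2 <- .parseCdsPos(m[3L])
    if (is.null(c1) || is.null(c2)) .hgvsParseError(text, "bad position")
    ch <- new("CodingChange", kind = "insertion", start = c1, end = c2,
              insLength = as.integer(m[4L]))
    flags <- c(flags, "length-only-insertion")
  } else if (length(m <- take(sprintf("^(%s)(?:_(%s))?([ACGTN]+)>([ACGTN]+)$",
                                      p, p)))) {
    ref <- m[4L]; alt <- m[5L]
    c1 <- .parseCdsPos(m[2L])
    if (is.null(c1)) .hgvsParseError(text, "bad position")
    if (m[3L] != "") {
      c2 <- .parseCdsPos(m[3L])
      if (is.null(c2)) .hgvsParseError(text, "bad position")
      flags <- c(flags, "substitution-style-indel")
    } else {
      c2 <- .coordAdd(c1, nchar(ref) - 1L)
      flags <- c(flags, "missing-del")
    }
    ch <- new("CodingChange", kind = "delins", start = c1, end = c2,
              refBases = ref, altBases = alt)
  } else {
    .hgvsParseError(text, "unrecognized change syntax")
  }

  new("HgvsExpression", accession = acc$accession, version = acc$version,
      molecule = molecule, change = ch, raw = text,
      dialectFlags = unique(flags))
}

.parseInterval <- function(text, p1, p2, bases) {
  c1 <- .parseCdsPos(p1)
  if (is.null(c1)) .hgvsParseError(text, "bad position")
  if (p2 != "") {
    c2 <- .parseCdsPos(p2)
    if (is.null(c2)) .hgvsParseError(text, "bad position")
  } else if (nzchar(bases) && nchar(bases) > 1L) {
    c2 <- .coordAdd(c1, nchar(bases) - 1L)
  } else {
    c2 <- c1
  }
  if (nzchar(bases)) {
    d <- .coordDiff(c1, c2)
    if (!is.na(d) && d + 1L != nchar(bases))
      .hgvsParseError(text, "stated bases disagree with the interval width")
  }
  list(start = c1, end = c2)
}

## ---------------------------------------------------------------------------
## Protein parsing
## ---------------------------------------------------------------------------

## Greedily read residue tokens (three-letter, one-letter, * or X) from the
## head of a string.  Returns residues as three-letter codes plus the unread
## remainder and the dialect flags used.
.takeResidues <- function(s) {
  res <- character(); flags <- character()
  repeat {
    if (nchar(s) >= 3L) {
      tok <- .normResidue3(substr(s, 1L, 3L))
      if (tok %in% c(.aminoAcids3, "Ter")) {
        res <- c(res, tok); s <- substr(s, 4L, nchar(s)); next
      }
    }
    c1 <- substr(s, 1L, 1L)
    if (c1 == "*") {
      res <- c(res, "Ter"); flags <- c(flags, "star-for-Ter")
      s <- substr(s, 2L, nchar(s)); next
    }
    if (c1 == "X") {
      res <- c(res, "Ter"); flags <- c(flags, "X-for-Ter")
      s <- substr(s, 2L, nchar(s)); next
    }
    if (c1 %in% .aminoAcids1) {
      res <- c(res, unname(.one2three[c1]))
      flags <- c(flags, "one-letter-aa")
      s <- substr(s, 2L, nchar(s)); next
    }
    break
  }
  list(res = res, rest = s, flags = flags)
}

.takeEndpoint <- function(s) {
  r <- .takeResidues(s)
  if (length(r$res) == 0L) return(NULL)
  m <- regmatches(r$rest, regexec("^([0-9]+)(.*)$", r$rest))[[1L]]
  if (length(m) == 0L) return(NULL)
  list(res = r$res, pos = as.integer(m[2L]), rest = m[3L], flags = r$flags)
}

#' Parse a protein (p.) HGVS expression
#'
#' One- and three-letter residue codes are both accepted; `*` and `X`
#' normalize to `Ter` with a dialect flag; `p.=`, `p.(=)`, `p.Arg317Arg` and
#' `p.Arg317=` all parse.
#'
#' @inheritParams parseCoding
#' @return an [HgvsExpression] carrying a [ProteinChange].
#' @examples
#' parseProtein("p.Arg227LysfsTer31")
#' parseProtein("p.*1133L")    # extension written as a stop substitution
#' parseProtein("p.Gln100*")
#' @export
parseProtein <- function(text) {
  cl <- .cleanHgvs(text)
  acc <- .splitAccession(cl$s)
  s <- acc$rest
  m <- regmatches(s, regexec("^p\\.(.+)$", s))[[1L]]
  if (length(m) == 0L) .hgvsParseError(text, "expected p. prefix")
  body <- m[2L]
  flags <- cl$flags
  if (grepl("^\\(.*\\)$", body)) {
    body <- substr(body, 2L, nchar(body) - 1L)
    flags <- c(flags, "parentheses")
  }

  done <- function(kind, startRes = NA_character_, startPos = NA_integer_,
                   endRes = NA_character_, endPos = NA_integer_,
                   altRes = character(), fsNewStop = NA_integer_,
                   fsLowerBound = FALSE, extNewStop = NA_integer_,
                   extra = character()) {
    ch <- new("ProteinChange", kind = kind, startRes = startRes,
              startPos = as.integer(startPos), endRes = endRes,
              endPos = as.integer(endPos), altRes = altRes,
              fsNewStop = as.integer(fsNewStop), fsLowerBound = fsLowerBound,
              extNewStop = as.integer(extNewStop))
    new("HgvsExpression", accession = acc$accession, version = acc$version,
        molecule = "p", change = ch, raw = text,
        dialectFlags = unique(c(flags, extra)))
  }

  if (body == "=") return(done("identity"))
  if (grepl("^(Met1|M1)\\?$", body))
    return(done("unknown-start", startRes = "Met", startPos = 1L,
                extra = if (startsWith(body, "M1")) "one-letter-aa"))

  e1 <- .takeEndpoint(body)
  if (is.null(e1)) .hgvsParseError(text, "no leading residue/position")
  flags <- c(flags, e1$flags)
  res1 <- e1$res
  pos1 <- e1$pos
  tail <- e1$rest

  e2 <- NULL
  if (startsWith(tail, "_")) {
    e2 <- .takeEndpoint(substr(tail, 2L, nchar(tail)))
    if (is.null(e2)) .hgvsParseError(text, "bad second endpoint")
    flags <- c(flags, e2$flags)
    tail <- e2$rest
  }
  startRes <- res1[1L]
  endRes <- if (!is.null(e2)) e2$res[1L] else res1[length(res1)]
  endPos <- if (!is.null(e2)) e2$pos else pos1 + length(res1) - 1L

  ## operator keywords
  if (tail == "=") {
    if (length(res1) != 1L || !is.null(e2))
      .hgvsParseError(text, "synonymous form names one residue")
    return(done("synonymous", startRes, pos1, startRes, pos1))
  }
  if (grepl("^delins", tail)) {
    r <- .takeResidues(substr(tail, 7L, nchar(tail)))
    if (length(r$res) == 0L || nzchar(r$rest))
      .hgvsParseError(text, "bad delins residues")
    return(done("delins", startRes, pos1, endRes, endPos, altRes = r$res,
                extra = r$flags))
  }
  if (grepl("^del", tail)) {
    r <- .takeResidues(substr(tail, 4L, nchar(tail)))
    if (nzchar(r$rest)) .hgvsParseError(text, "bad deletion tail")
    extra <- r$flags
    if (length(r$res)) extra <- c(extra, "restated-residues")
    return(done("deletion", startRes, pos1, endRes, endPos, extra = extra))
  }
  if (grepl("^dup", tail)) {
    r <- .takeResidues(substr(tail, 4L, nchar(tail)))
    if (nzchar(r$rest)) .hgvsParseError(text, "bad duplication tail")
    extra <- r$flags
    if (length(r$res)) extra <- c(extra, "restated-residues")
    return(done("duplication", startRes, pos1, endRes, endPos,
                extra = extra))
  }
  if (grepl("^ins", tail)) {
    r <- .takeResidues(substr(tail, 4L, nchar(tail)))
    if (length(r$res) == 0L || nzchar(r$rest))
      .hgvsParseError(text, "bad insertion residues")
    if (is.null(e2))
      .hgvsParseError(text, "insertion needs two flanking residues")
    return(done("insertion", startRes, pos1, endRes, endPos,
                altRes = r$res, extra = r$flags))
  }
  if (grepl("fs", tail) || grepl("ext", tail)) {
    r <- .takeResidues(tail)
    altr <- r$res
    flags <- c(flags, r$flags)
    op <- r$rest
    if (op == "fs") {
      if (length(altr) > 1L) .hgvsParseError(text, "bad frameshift residues")
      return(done("frameshift", startRes, pos1, startRes, pos1,
                  altRes = altr))
    }
    m <- regmatches(op, regexec("^fs(Ter|\\*)([0-9]+|\\?)$", op))[[1L]]
    if (length(m)) {
      if (length(altr) > 1L) .hgvsParseError(text, "bad frameshift residues")
      extra <- if (m[2L] == "*") "star-for-Ter" else character()
      stp <- if (m[3L] == "?") NA_integer_ else as.integer(m[3L])
      return(done("frameshift", startRes, pos1, startRes, pos1,
                  altRes = altr, fsNewStop = stp, extra = extra))
    }
    m <- regmatches(op, regexec("^fs\\*>([0-9]+)$", op))[[1L]]
    if (length(m)) {
      if (length(altr) > 1L) .hgvsParseError(text, "bad frameshift residues")
      return(done("frameshift", startRes, pos1, startRes, pos1,
                  altRes = altr, fsNewStop = as.integer(m[2L]),
                  fsLowerBound = TRUE, extra = "fs-lower-bound"))
    }
    m <- regmatches(op, regexec("^ext(Ter|\\*)([0-9]+|\\?)$", op))[[1L]]
    if (length(m)) {
      if (length(altr) != 1L) .hgvsParseError(text, "bad extension residue")
      if (startRes != "Ter")
        .hgvsParseError(text, "extension must start at the stop codon")
      extra <- if (m[2L] == "*") "star-for-Ter" else character()
      stp <- if (m[3L] == "?") NA_integer_ else as.integer(m[3L])
      return(done("extension", "Ter", pos1, "Ter", pos1, altRes = altr,
                  extNewStop = stp, extra = extra))
    }
    .hgvsParseError(text, "bad frameshift/extension tail")
  }
  if (startsWith(tail, ">")) {
    r <- .takeResidues(substr(tail, 2L, nchar(tail)))
    if (length(r$res) == 0L || nzchar(r$rest))
      .hgvsParseError(text, "bad substitution-style residues")
    return(done("delins", startRes, pos1, endRes, endPos, altRes = r$res,
                extra = c(r$flags, "substitution-style-indel")))
  }
  if (tail == "" && is.null(e2)) {
    ## bare residues after the position: substitution and its dialects
    nref <- length(res1) - 1L  # residues beyond the first belong to alt? no:
    ## res1 are the leading (reference) residues; a bare tail means the
    ## parse consumed everything before the digits, so alt residues follow
    ## the position only when tail was non-empty.  A single leading residue
    ## with empty tail is unparseable.
    .hgvsParseError(text, "missing consequence after the position")
  }
  if (nzchar(tail)) {
    r <- .takeResidues(tail)
    if (nzchar(r$rest)) .hgvsParseError(text, "unrecognized protein syntax")
    alt <- r$res
    flags <- c(flags, r$flags)
    if (!is.null(e2)) {
      ## interval followed by residues without an operator: not HGVS
      .hgvsParseError(text, "interval change needs an operator")
    }
    if (length(res1) > 1L) {
      ## e.g. p.AspAla2625GluPro: MNV written as a multi-residue substitution
      return(done("delins", res1[1L], pos1, res1[length(res1)],
                  pos1 + length(res1) - 1L, altRes = alt,
                  extra = "substitution-style-indel"))
    }
    if (length(alt) == 1L) {
      if (alt == startRes)
        return(done("synonymous", startRes, pos1, startRes, pos1,
                    extra = "redundant-alt"))
      if (startRes == "Ter")
        return(done("extension", "Ter", pos1, "Ter", pos1, altRes = alt,
                    extra = "ext-substitution-dialect"))
      return(done("substitution", startRes, pos1, startRes, pos1,
                  altRes = alt))
    }
    return(done("delins", startRes, pos1, startRes, pos1, altRes = alt,
                extra = "substitution-style-indel"))
  }
  .hgvsParseError(text, "unrecognized protein syntax")
}

#' Parse any HGVS expression
#'
#' Dispatches on the molecule prefix (`c.`, `g.` or `p.`).
#'
#' @inheritParams parseCoding
#' @return an [HgvsExpression].
#' @export
parseHgvs <- function(text) {
  s <- .splitAccession(gsub("[[:space:]]+", "", text))$rest
  if (grepl("^p\\.", s)) parseProtein(text) else parseCoding(text)
}
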