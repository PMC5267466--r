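## Emission of the single preferred HGVS form.
##
## Style: three-letter residues, Ter (never * or X), delins and dup without
## restating the removed/duplicated bases, deletions retaining their bases
## when known, synonymous as "p.Thr258=", frameshift long form when the new
## stop is known and short form otherwise, no parentheses, no whitespace.

#' Format a coding coordinate
#' @param coord a [CdsCoord].
#' @return HGVS position text such as `"1895+5"`, `"-14"` or `"*4"`.
#' @export
formatCdsCoord <- function(coord) {
  paste0(if (coord@star) "*" else "", coord@anchor,
         if (coord@offset != 0L) sprintf("%+d", coord@offset) else "")
}

.formatCodingInterval <- function(ch) {
  a <- formatCdsCoord(ch@start)
  if (ch@kind == "insertion" || !.coordEqual(ch@start, ch@end))
    paste0(a, "_", formatCdsCoord(ch@end))
  else a
}

.formatCodingChange <- function(ch, keepDelBases = TRUE) {
  iv <- .formatCodingInterval(ch)
  switch(ch@kind,
    substitution = paste0(iv, ch@refBases, ">", ch@altBases),
    identity = paste0(iv,
                      if (!is.na(ch@refBases)) ch@refBases else "", "="),
    deletion = paste0(iv, "del",
                      if (keepDelBases && !is.na(ch@refBases))
                        ch@refBases else ""),
    duplication = paste0(iv, "dup"),
    insertion = paste0(iv, "ins",
                       if (!is.na(ch@altBases)) ch@altBases
                       else ch@insLength),
    delins = paste0(iv, "delins", ch@altBases),
    stop("unknown coding change kind"))
}

.formatProteinChange <- function(ch) {
  p1 <- paste0(ch@startRes, ch@startPos)
  iv <- if (!is.na(ch@endPos) && ch@endPos != ch@startPos)
    paste0(p1, "_", ch@endRes, ch@endPos) else p1
  alt <- paste(ch@altRes, collapse = "")
  switch(ch@kind,
    identity = "=",
    synonymous = paste0(p1, "="),
    substitution = paste0(p1, alt),
    deletion = paste0(iv, "del"),
    duplication = paste0(iv, "dup"),
    insertion = paste0(iv, "ins", alt),
    delins = paste0(iv, "delins", alt),
    frameshift =
      if (length(ch@altRes) == 1L && !is.na(ch@fsNewStop) &&
          !ch@fsLowerBound)
        paste0(p1, alt, "fsTer", ch@fsNewStop)
      else paste0(p1, "fs"),
    extension = paste0(p1, alt, "extTer",
                       if (is.na(ch@extNewStop)) "?" else ch@extNewStop),
    `unknown-start` = "Met1?",
    stop("unknown protein change kind"))
}

#' Emit the preferred HGVS syntax for an expression
#'
#' Total on structurally valid changes; the output re-parses to the same
#' change with no dialect flags.
#'
#' @param expr an [HgvsExpression].
#' @param keepDelBases retain deleted bases on coding deletions when they are
#'   known (the configurable deletion style; duplications and delins never
#'   restate bases).
#' @return character HGVS text.
#' @examples
#' formatPreferred(parseCoding("c.68-5_68-3delCTCinsTT"))
#' # "c.68-5_68-3delinsTT"
#' @export
formatPreferred <- function(expr, keepDelBases = TRUE) {
  body <- if (expr@molecule == "p") .formatProteinChange(expr@change)
          else .formatCodingChange(expr@change, keepDelBases)
  prefix <- ""
  if (!is.na(expr@accession)) {
    prefix <- paste0(expr@accession,
                     if (!is.na(expr@version)) paste0(".", expr@version)
                     else "", ":")
  }
  paste0(prefix, expr@molecule, ".", body)
}
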