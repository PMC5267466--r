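## Dataset-scale pipeline: read database-style annotation tables, join them
## to VCF variants, run the comparator, and summarize concordance by variant
## type and level (coding / protein).

.annDialects <- c("clinvar-like", "cosmic-like", "tool-like")

#' Read a database-style annotation table
#'
#' Tab-separated, one annotation per row.  Column mapping per dialect:
#' \describe{
#'   \item{clinvar-like}{`rsid`, `alt` (a hyphen `-` represents the
#'     alternative allele of deletions), `transcript`, `coding_hgvs`,
#'     `protein_hgvs`.}
#'   \item{cosmic-like}{`cosmid`, `transcript`, `coding_hgvs`,
#'     `protein_hgvs`; one-letter protein syntax is converted to
#'     three-letter residues on read when the expression is otherwise
#'     preferred.}
#'   \item{tool-like}{`id`, `alt`, `transcript`, `coding_hgvs`,
#'     `protein_hgvs`.}
#' }
#' Malformed rows are kept with `rowStatus = "malformed"` and counted, never
#' dropped silently.
#'
#' @param path TSV file.
#' @param dialect one of `"clinvar-like"`, `"cosmic-like"`, `"tool-like"`.
#' @return data.frame with columns source, id, alt, transcript, coding,
#'   protein, rowStatus; the number of malformed rows is attached as
#'   attribute `nMalformed`.
#' @export
readAnnotationTable <- function(path, dialect = .annDialects) {
  dialect <- match.arg(dialect)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  idCol <- switch(dialect, "clinvar-like" = "rsid",
                  "cosmic-like" = "cosmid", "tool-like" = "id")
  needed <- c(idCol, "transcript", "coding_hgvs", "protein_hgvs")
  missing <- setdiff(needed, names(raw))
  if (length(missing))
    stop("annotation table lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  n <- nrow(raw)
  alt <- if ("alt" %in% names(raw)) raw[["alt"]] else rep(NA_character_, n)
  out <- data.frame(source = rep(dialect, n),
                    id = raw[[idCol]],
                    alt = alt,
                    transcript = raw[["transcript"]],
                    coding = raw[["coding_hgvs"]],
                    protein = raw[["protein_hgvs"]],
                    rowStatus = rep("ok", n),
                    stringsAsFactors = FALSE)
  bad <- !nzchar(out$id) | is.na(out$id) |
    (!nzchar(out$coding) & !nzchar(out$protein))
  out$rowStatus[bad] <- "malformed"
  if (dialect == "cosmic-like") {
    conv <- c("one-letter-aa", "star-for-Ter", "X-for-Ter")
    out$protein <- vapply(out$protein, function(p) {
      if (is.na(p) || !nzchar(p)) return(p)
      e <- tryCatch(parseProtein(p), hgvsParseError = function(err) NULL)
      if (!is.null(e) && length(e@dialectFlags) &&
          all(e@dialectFlags %in% conv))
        formatPreferred(e)
      else p
    }, character(1L), USE.NAMES = FALSE)
  }
  attr(out, "nMalformed") <- sum(bad)
  out
}

## Accept both the reader layout (coding/protein) and the generator layout
## (coding_hgvs/protein_hgvs); default rowStatus to "ok".
.asRecords <- function(records) {
  if (is.null(records$coding) && !is.null(records$coding_hgvs))
    records$coding <- records$coding_hgvs
  if (is.null(records$protein) && !is.null(records$protein_hgvs))
    records$protein <- records$protein_hgvs
  if (is.null(records$rowStatus))
    records$rowStatus <- rep("ok", nrow(records))
  if (is.null(records$alt))
    records$alt <- rep(NA_character_, nrow(records))
  records
}

#' Join VCF variants to annotation records
#'
#' clinvar-like records join on (rsid, alternative allele) with the hyphen
#' convention for deletion alleles; cosmic-like records join on the COSMID
#' alone, regardless of position representation (normalization reconciles
#' positions).  Both sides must be de-duplicated first.  Ambiguous record
#' keys keep the first occurrence (input order is preserved) and are
#' flagged; unmatched records are reported with reasons.
#'
#' @param variants normalized variant table (ids possibly `;`-joined by
#'   [dedupeVariants()]).
#' @param records annotation records from [readAnnotationTable()].
#' @return list with `pairs` (variantRow, recordRow), `unmatched`
#'   (recordRow, reason) and `ambiguous` (recordRow).
#' @export
joinAnnotations <- function(variants, records) {
  records <- .asRecords(records)
  vIds <- strsplit(ifelse(is.na(variants$id), "", variants$id), ";",
                   fixed = TRUE)
  vTypes <- variantType(variants)
  pairs <- data.frame(variantRow = integer(), recordRow = integer())
  unmatched <- data.frame(recordRow = integer(), reason = character())
  ambiguous <- integer()
  seenKeys <- character()
  for (j in seq_len(nrow(records))) {
    if (records$rowStatus[j] != "ok") {
      unmatched <- rbind(unmatched,
                         data.frame(recordRow = j, reason = "malformed"))
      next
    }
    key <- paste0(records$id[j], "\r", records$alt[j], "\r",
                  records$transcript[j])
    if (key %in% seenKeys) {
      ambiguous <- c(ambiguous, j)
      unmatched <- rbind(unmatched,
                         data.frame(recordRow = j,
                                    reason = "duplicate-key"))
      next
    }
    seenKeys <- c(seenKeys, key)
    hit <- which(vapply(vIds, function(x) records$id[j] %in% x,
                        logical(1L)))
    if (length(hit) == 0L) {
      unmatched <- rbind(unmatched,
                         data.frame(recordRow = j, reason = "no-id-match"))
      next
    }
    if (!is.na(records$alt[j]) && nzchar(records$alt[j])) {
      keep <- if (records$alt[j] == "-") {
        hit[vTypes[hit] == "deletion"]
      } else {
        hit[vapply(hit, function(i) {
          ref <- variants$ref[i]; alt <- variants$alt[i]
          alt == records$alt[j] ||
            (nchar(alt) > 1L && substr(alt, 2L, nchar(alt)) ==
               records$alt[j])
        }, logical(1L))]
      }
      if (length(keep) == 0L) {
        unmatched <- rbind(unmatched,
                           data.frame(recordRow = j,
                                      reason = "no-alt-match"))
        next
      }
      hit <- keep
    }
    pairs <- rbind(pairs, data.frame(variantRow = hit[1L], recordRow = j))
  }
  list(pairs = pairs, unmatched = unmatched, ambiguous = ambiguous)
}

.lookupTranscript <- function(transcripts, txLabel) {
  if (txLabel %in% names(transcripts))
    return(list(tx = transcripts[[txLabel]], reason = NULL))
  acc <- sub("\\.[0-9]+$", "", txLabel)
  accs <- vapply(transcripts, function(t) t@accession, character(1L))
  if (acc %in% accs)
    return(list(tx = NULL, reason = "transcript-version-mismatch"))
  list(tx = NULL, reason = "transcript-accession-unknown")
}

#' Evaluate annotation concordance
#'
#' In `generate` mode the VCF side of each joined pair is annotated with
#' [annotateVariant()] and the record's coding/protein syntax is compared
#' against the generated annotation.  In `compare` mode two annotation
#' tables are matched by id and compared directly.  Pairs whose transcript
#' accession or version is absent from `transcripts` are `not_assessed` and
#' excluded from concordance denominators (but always reported).  When a
#' source provides multiple annotations per variant and transcript the
#' first is evaluated.
#'
#' @param records query annotation records ([readAnnotationTable()] layout).
#' @param transcripts named list of [TranscriptModel]s keyed by
#'   `accession.version`.
#' @param genome named [Biostrings::DNAStringSet].
#' @param variants normalized variant table (`generate` mode).
#' @param reference reference annotation records (`compare` mode).
#' @param mode `"generate"` or `"compare"`.
#' @return list of class `concordanceResult`: `summary` (per type x level
#'   verdict counts and fractions), `verdicts` (per-record table with reason
#'   tags), `unmatched`, `log`.
#' @export
evaluateConcordance <- function(records, transcripts, genome = NULL,
                                variants = NULL, reference = NULL,
                                mode = c("generate", "compare")) {
  mode <- match.arg(mode)
  records <- .asRecords(records)
  if (!is.null(reference)) reference <- .asRecords(reference)
  verdicts <- NULL
  unmatched <- data.frame(recordRow = integer(), reason = character())

  addVerdict <- function(id, type, transcript, level, v) {
    data.frame(id = id, type = type, transcript = transcript,
               level = level, status = verdictStatus(v),
               reasons = paste(verdictReasons(v), collapse = ","),
               stringsAsFactors = FALSE)
  }

  if (mode == "generate") {
    stopifnot(!is.null(variants), !is.null(genome))
    jn <- joinAnnotations(variants, records)
    unmatched <- jn$unmatched
    rows <- list()
    ctxCache <- list()
    for (k in seq_len(nrow(jn$pairs))) {
      i <- jn$pairs$variantRow[k]; j <- jn$pairs$recordRow[k]
      v <- variants[i, , drop = FALSE]
      type <- variantType(v, genome)
      lk <- .lookupTranscript(transcripts, records$transcript[j])
      if (is.null(lk$tx)) {
        na <- MatchVerdict("not_assessed", lk$reason)
        for (lvl in c("coding", "protein"))
          rows[[length(rows) + 1L]] <-
            addVerdict(records$id[j], type, records$transcript[j], lvl, na)
        next
      }
      txLab <- records$transcript[j]
      if (is.null(ctxCache[[txLab]]))
        ctxCache[[txLab]] <- .txContext(lk$tx, genome)
      ann <- annotateVariant(v, lk$tx, genome, ctx = ctxCache[[txLab]])
      if (ann@status == "not_assessed") {
        na <- MatchVerdict("not_assessed", "outside-transcript-locus")
        rows[[length(rows) + 1L]] <-
          addVerdict(records$id[j], type, records$transcript[j], "coding",
                     na)
        next
      }
      rows[[length(rows) + 1L]] <- addVerdict(
        records$id[j], type, records$transcript[j], "coding",
        .compareLevel(records$coding[j],
                      if (is.null(ann@coding)) NULL
                      else formatPreferred(ann@coding)))
      rows[[length(rows) + 1L]] <- addVerdict(
        records$id[j], type, records$transcript[j], "protein",
        .compareLevel(records$protein[j],
                      if (is.null(ann@protein)) NULL
                      else formatPreferred(ann@protein)))
    }
    verdicts <- if (length(rows)) do.call(rbind, rows) else
      .emptyVerdicts()
  } else {
    stopifnot(!is.null(reference))
    refIdx <- match(records$id, reference$id)
    rows <- list()
    for (j in seq_len(nrow(records))) {
      if (records$rowStatus[j] != "ok") {
        unmatched <- rbind(unmatched,
                           data.frame(recordRow = j, reason = "malformed"))
        next
      }
      i <- refIdx[j]
      if (is.na(i)) {
        unmatched <- rbind(unmatched,
                           data.frame(recordRow = j,
                                      reason = "no-id-match"))
        next
      }
      type <- .typeFromCoding(reference$coding[i])
      if (!identical(records$transcript[j], reference$transcript[i])) {
        qa <- .splitAccession(records$transcript[j])
        ra <- .splitAccession(reference$transcript[i])
        reason <- if (!is.na(qa$accession) && !is.na(ra$accession) &&
                      sub("\\..*$", "", records$transcript[j]) ==
                      sub("\\..*$", "", reference$transcript[i]))
          "transcript-version-mismatch" else "transcript-accession-mismatch"
        na <- MatchVerdict("not_assessed", reason)
        for (lvl in c("coding", "protein"))
          rows[[length(rows) + 1L]] <-
            addVerdict(records$id[j], type, records$transcript[j], lvl, na)
        next
      }
      rows[[length(rows) + 1L]] <- addVerdict(
        records$id[j], type, records$transcript[j], "coding",
        .compareLevel(records$coding[j], reference$coding[i]))
      rows[[length(rows) + 1L]] <- addVerdict(
        records$id[j], type, records$transcript[j], "protein",
        .compareLevel(records$protein[j], reference$protein[i]))
    }
    verdicts <- if (length(rows)) do.call(rbind, rows) else
      .emptyVerdicts()
  }

  rownames(verdicts) <- NULL
  out <- list(summary = summarizeConcordance(verdicts),
              verdicts = verdicts, unmatched = unmatched,
              log = c(pairs = nrow(verdicts) / 2L,
                      unmatched = nrow(unmatched)))
  class(out) <- "concordanceResult"
  out
}

.emptyVerdicts <- function()
  data.frame(id = character(), type = character(), transcript = character(),
             level = character(), status = character(),
             reasons = character(), stringsAsFactors = FALSE)

## Compare one level (coding or protein) of a record against the reference,
## handling absent annotations on either side.
.compareLevel <- function(queryText, referenceText) {
  qEmpty <- is.null(queryText) || is.na(queryText) || !nzchar(queryText)
  rEmpty <- is.null(referenceText) || is.na(referenceText) ||
    !nzchar(referenceText)
  if (qEmpty && rEmpty) return(MatchVerdict("exact"))
  if (qEmpty) return(MatchVerdict("incorrect", "missing-annotation"))
  if (rEmpty) return(MatchVerdict("incorrect", "spurious-annotation"))
  compareExpressions(queryText, referenceText)
}

## Variant type as implied by a parsed coding expression (compare mode,
## where no VCF alleles are available).
.typeFromCoding <- function(text) {
  if (is.na(text) || !nzchar(text)) return("unknown")
  e <- tryCatch(parseCoding(text), hgvsParseError = function(err) NULL)
  if (is.null(e)) return("unknown")
  ch <- e@change
  switch(ch@kind,
    substitution = "SNV",
    identity = "SNV",
    deletion = "deletion",
    duplication = "duplication",
    insertion = "insertion",
    delins = {
      w <- .coordDiff(ch@start, ch@end)
      if (!is.na(w) && !is.na(ch@altBases) && w + 1L == nchar(ch@altBases))
        "MNV" else "delins"
    },
    "unknown")
}

#' Summarize verdicts by variant type and level
#'
#' @param verdicts per-record verdict table from [evaluateConcordance()].
#' @return data.frame with one row per (type, level): verdict counts,
#'   fractions over all joined records (summing to 1), and fractions over
#'   assessed records (not_assessed excluded from the denominator).
#' @export
summarizeConcordance <- function(verdicts) {
  lv <- .verdictStatuses
  cells <- unique(verdicts[, c("type", "level")])
  cells <- cells[order(cells$type, cells$level), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(k) {
    sel <- verdicts$type == cells$type[k] & verdicts$level == cells$level[k]
    n <- sum(sel)
    counts <- vapply(lv, function(s) sum(verdicts$status[sel] == s),
                     integer(1L))
    nAssessed <- n - counts[["not_assessed"]]
    fr <- counts / max(n, 1L)
    frA <- counts / max(nAssessed, 1L)
    data.frame(type = cells$type[k], level = cells$level[k], n = n,
               nAssessed = nAssessed,
               exact = counts[["exact"]], equivalent = counts[["equivalent"]],
               incorrect = counts[["incorrect"]],
               not_assessed = counts[["not_assessed"]],
               fracExact = fr[["exact"]], fracEquivalent = fr[["equivalent"]],
               fracIncorrect = fr[["incorrect"]],
               fracNotAssessed = fr[["not_assessed"]],
               assessedExact = frA[["exact"]],
               assessedEquivalent = frA[["equivalent"]],
               assessedIncorrect = frA[["incorrect"]],
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(), level = character())
  rownames(out) <- NULL
  out
}

#' @export
print.concordanceResult <- function(x, ...) {
  cat("Concordance result: ", x$log[["pairs"]], " pair(s), ",
      x$log[["unmatched"]], " unmatched record(s)\n", sep = "")
  print(x$summary, ...)
  invisible(x)
}

#' Write a concordance report
#'
#' Machine-readable JSON (summary, log, unmatched) plus a human-readable TSV
#' verdict table with reason tags for audit.
#'
#' @param result a `concordanceResult` from [evaluateConcordance()].
#' @param prefix output path prefix; writes `<prefix>.json` and
#'   `<prefix>_verdicts.tsv`.
#' @return invisibly, the two file paths.
#' @export
writeConcordanceReport <- function(result, prefix) {
  jsonPath <- paste0(prefix, ".json")
  tsvPath <- paste0(prefix, "_verdicts.tsv")
  jsonlite::write_json(list(summary = result$summary,
                            log = as.list(result$log),
                            unmatched = result$unmatched),
                       jsonPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  utils::write.table(result$verdicts, tsvPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(jsonPath, tsvPath))
}

#' Read back a concordance report
#'
#' @param prefix the prefix passed to [writeConcordanceReport()].
#' @return list with `summary`, `log` and `verdicts` equal (after type
#'   coercion) to the written result.
#' @export
readConcordanceReport <- function(prefix) {
  js <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  verdicts <- utils::read.delim(paste0(prefix, "_verdicts.tsv"),
                                stringsAsFactors = FALSE,
                                colClasses = "character")
  list(summary = as.data.frame(js$summary), log = js$log,
       verdicts = verdicts)
}
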