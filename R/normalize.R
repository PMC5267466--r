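## VCF-convention allele normalization: vt-style left alignment,
## de-duplication, and phased multinucleotide-variant merging.
##
## Variant tables are plain data.frames with columns contig, pos (1-based),
## ref, alt, id (optional provenance identifier, NA allowed) and phaseGroup
## (optional phase-set label, NA when unphased).

#' Build a variant table
#'
#' @param contig,pos,ref,alt,id,phaseGroup per-variant vectors; `id` and
#'   `phaseGroup` default to `NA`.
#' @return data.frame with the canonical variant-table columns.
#' @export
variantTable <- function(contig, pos, ref, alt, id = NA_character_,
                         phaseGroup = NA_character_) {
  data.frame(contig = as.character(contig), pos = as.integer(pos),
             ref = toupper(as.character(ref)),
             alt = toupper(as.character(alt)),
             id = as.character(id), phaseGroup = as.character(phaseGroup),
             stringsAsFactors = FALSE)
}

.refMismatch <- function(msg) {
  structure(class = c("referenceMismatch", "error", "condition"),
            list(message = msg, call = NULL))
}

.gbase <- function(genome, contig, from, to = from) {
  as.character(Biostrings::subseq(genome[[contig]], from, to))
}

.leftAlignOne <- function(contig, pos, ref, alt, genome) {
  if (.gbase(genome, contig, pos, pos + nchar(ref) - 1L) != ref)
    stop(.refMismatch(sprintf("ref allele disagrees with genome at %s:%d",
                              contig, pos)))
  repeat {
    changed <- FALSE
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0L && na > 0L &&
        substr(ref, nr, nr) == substr(alt, na, na)) {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
      changed <- TRUE
    }
    if (nchar(ref) == 0L || nchar(alt) == 0L) {
      if (pos == 1L) {
        ## cannot extend further left; re-anchor on the right instead
        b <- .gbase(genome, contig, pos + nchar(ref))
        ref <- paste0(ref, b); alt <- paste0(alt, b)
        break
      }
      pos <- pos - 1L
      b <- .gbase(genome, contig, pos)
      ref <- paste0(b, ref); alt <- paste0(b, alt)
      changed <- TRUE
    }
    if (!changed) break
  }
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Left-align variants against the genome
#'
#' The vt-normalize algorithm: shared right flanks are trimmed (extending
#' left through the reference when an allele empties), then shared left
#' flanks beyond the single anchor base are trimmed.  The result is
#' parsimonious, left-most and idempotent.
#'
#' @param variants a variant table (see [variantTable()]).
#' @param genome named [Biostrings::DNAStringSet].
#' @return the variant table with normalized `pos`, `ref`, `alt`.
#' @export
leftAlign <- function(variants, genome) {
  for (i in seq_len(nrow(variants))) {
    la <- .leftAlignOne(variants$contig[i], variants$pos[i],
                        variants$ref[i], variants$alt[i], genome)
    variants$pos[i] <- la$pos
    variants$ref[i] <- la$ref
    variants$alt[i] <- la$alt
  }
  variants
}

#' De-duplicate a variant table
#'
#' Unique on (contig, pos, ref, alt); the key deliberately ignores `id`, and
#' colliding ids are concatenated (`;`-joined) as provenance.
#'
#' @param variants a left-aligned variant table.
#' @return de-duplicated variant table, input order of first occurrences
#'   preserved.
#' @export
dedupeVariants <- function(variants) {
  if (nrow(variants) == 0L) return(variants)
  key <- paste(variants$contig, variants$pos, variants$ref, variants$alt,
               sep = "\r")
  keep <- !duplicated(key)
  out <- variants[keep, , drop = FALSE]
  ids <- split(variants$id, factor(key, levels = key[keep]))
  out$id <- vapply(ids, function(x) {
    x <- unique(x[!is.na(x)])
    if (length(x) == 0L) NA_character_ else paste(x, collapse = ";")
  }, character(1L))
  rownames(out) <- NULL
  out
}

#' Merge phased adjacent SNVs into block substitutions
#'
#' Adjacent single-nucleotide variants sharing a `phaseGroup` label merge
#' into one multinucleotide substitution (MNV); unphased or non-adjacent
#' neighbours stay separate.  The edited-sequence outcome of the record set
#' is unchanged.
#'
#' @param variants a sorted variant table.
#' @return variant table with phased runs collapsed.
#' @export
mergePhasedMnv <- function(variants) {
  if (nrow(variants) <= 1L) return(variants)
  o <- order(variants$contig, variants$pos)
  v <- variants[o, , drop = FALSE]
  isSnv <- nchar(v$ref) == 1L & nchar(v$alt) == 1L
  grp <- seq_len(nrow(v))
  for (i in 2L:nrow(v)) {
    if (isSnv[i] && isSnv[i - 1L] &&
        v$contig[i] == v$contig[i - 1L] &&
        v$pos[i] == v$pos[i - 1L] + 1L &&
        !is.na(v$phaseGroup[i]) && !is.na(v$phaseGroup[i - 1L]) &&
        v$phaseGroup[i] == v$phaseGroup[i - 1L])
      grp[i] <- grp[i - 1L]
    if (v$contig[i] == v$contig[i - 1L] &&
        v$pos[i] == v$pos[i - 1L] && v$ref[i] == v$ref[i - 1L] &&
        v$alt[i] != v$alt[i - 1L] &&
        !is.na(v$phaseGroup[i]) && !is.na(v$phaseGroup[i - 1L]) &&
        v$phaseGroup[i] == v$phaseGroup[i - 1L])
      stop("overlapping conflicting records in one phase group at ",
           v$contig[i], ":", v$pos[i])
  }
  pieces <- lapply(split(seq_len(nrow(v)), grp), function(ix) {
    if (length(ix) == 1L) return(v[ix, , drop = FALSE])
    ids <- unique(v$id[ix][!is.na(v$id[ix])])
    variantTable(v$contig[ix[1L]], v$pos[ix[1L]],
                 paste(v$ref[ix], collapse = ""),
                 paste(v$alt[ix], collapse = ""),
                 id = if (length(ids)) paste(ids, collapse = ";")
                      else NA_character_,
                 phaseGroup = v$phaseGroup[ix[1L]])
  })
  out <- do.call(rbind, pieces[order(as.integer(names(pieces)))])
  rownames(out) <- NULL
  out
}

#' Full VCF-side normalization
#'
#' Left-aligns, merges phased MNVs and de-duplicates, in that order.
#'
#' @inheritParams leftAlign
#' @return normalized variant table.
#' @export
normalizeVariants <- function(variants, genome) {
  dedupeVariants(mergePhasedMnv(leftAlign(variants, genome)))
}

#' Classify a normalized variant's type
#'
#' Types are computed from the normalized alleles (never trusted from source
#' labels): SNV, MNV, deletion, insertion, duplication, delins.  Duplication
#' calls verify the inserted bases against the reference after right
#' shifting; without a genome multi-base insertions stay insertions.
#'
#' @param variants variant table.
#' @param genome optional genome for duplication verification.
#' @return character vector of types.
#' @export
variantType <- function(variants, genome = NULL) {
  vapply(seq_len(nrow(variants)), function(i) {
    ref <- variants$ref[i]; alt <- variants$alt[i]
    nr <- nchar(ref); na <- nchar(alt)
    if (nr == 1L && na == 1L) return("SNV")
    if (nr == na) return("MNV")
    if (nr < na && startsWith(alt, ref)) {
      ins <- substr(alt, nr + 1L, na)
      if (!is.null(genome) &&
          .isDupIns(variants$contig[i], variants$pos[i] + nr - 1L, ins,
                    genome))
        return("duplication")
      return("insertion")
    }
    if (na < nr && startsWith(ref, alt)) return("deletion")
    "delins"
  }, character(1L))
}

## Right-shift an insertion (after genomic position p, inserted bases I) and
## test whether it duplicates the immediately preceding reference bases.
.isDupIns <- function(contig, p, ins, genome) {
  n <- nchar(ins)
  len <- length(genome[[contig]])
  while (p + 1L <= len && .gbase(genome, contig, p + 1L) ==
         substr(ins, 1L, 1L)) {
    ins <- paste0(substr(ins, 2L, n), substr(ins, 1L, 1L))
    p <- p + 1L
  }
  p >= n && .gbase(genome, contig, p - n + 1L, p) == ins
}
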