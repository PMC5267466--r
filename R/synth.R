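## Synthetic-data generator: fixture genomes with planted repeat contexts,
## transcript models (including a transcript-versus-genome reference
## override), truth variant sets with canonical annotations, and corrupted
## database-style annotation tables with known, labelled error modes.
##
## The fixture hard-codes the edge-case loci whose local sequence context
## the study states: a GTGA tandem at a donor site, a G run spanning an
## acceptor junction, a CCCC exonic homopolymer, a 9-mer duplication locus
## whose residues are Gly-Ser-Pro, a reference-override base, and a
## Val-encoding codon 600 for phased-MNV behaviour.  Background sequence is
## seeded pseudo-randomly; the planted loci are identical under every seed.

.errorModes <- c("no-right-shift", "over-shift-11", "dup-as-ins",
                 "ins-as-dup-redundant-delins",
                 "indel-as-substitution-dialect", "fs-short-form",
                 "one-letter-protein", "star-for-Ter",
                 "missing-del-designator", "version-bump",
                 "protein-for-intronic")

#' Simulation configuration
#'
#' @param seed integer seed for all pseudo-randomness (per-record sub-seeds
#'   are derived deterministically).
#' @param counts named integer vector of truth-record counts per class:
#'   `snv`, `nonsense`, `deletion`, `duplication`, `insertion`, `delins`,
#'   `mnv`, `intronic`, `utr`.  The default totals 126 records spread
#'   across variant types and genomic features, mirroring a curated
#'   ground-truth design.
#' @param rates named list of corruption rates in `[0, 1]` per error mode
#'   (see [corruptAnnotations()]); defaults are illustrative at 0.1 each.
#' @return a `SimulationConfig` list.
#' @export
simulationConfig <- function(seed = 1L,
                             counts = c(snv = 30L, nonsense = 10L,
                                        deletion = 24L, duplication = 18L,
                                        insertion = 12L, delins = 12L,
                                        mnv = 8L, intronic = 8L, utr = 4L),
                             rates = NULL) {
  if (is.null(rates))
    rates <- stats::setNames(as.list(rep(0.1, length(.errorModes))),
                             .errorModes)
  stopifnot(all(unlist(rates) >= 0), all(unlist(rates) <= 1),
            all(counts >= 0))
  unknown <- setdiff(names(rates), .errorModes)
  if (length(unknown)) stop("unknown error mode(s): ",
                            paste(unknown, collapse = ", "))
  structure(list(seed = as.integer(seed), counts = counts, rates = rates),
            class = "SimulationConfig")
}

.senseCodons <- function() {
  all <- as.character(Biostrings::GENETIC_CODE)
  names(Biostrings::GENETIC_CODE)[all != "*"]
}

## ------------------------------------------------------------------------
## fixture construction
## ------------------------------------------------------------------------

## txA planted codons (codon index -> triplet); see file header.
.txaPlanted <- c(
  "1" = "ATG",  "55" = "ATA", "56" = "GCT",
  "134" = "ATC", "135" = "CCC", "136" = "ATG",
  "141" = "CTA", "142" = "AAA", "143" = "AAG",
  "308" = "GGT", "309" = "CGT", "310" = "CGA", "311" = "CGG",
  "312" = "AAA", "317" = "CGC",
  "400" = "CTG", "401" = "GAT",
  "541" = "GAT",
  "600" = "GTG",
  "632" = "GAA",
  "649" = "GAT", "650" = "AGC", "651" = "AGC", "652" = "AGC",
  "653" = "GGT",
  "754" = "ACA", "755" = "TTT",
  "777" = "CAG", "778" = "GGC", "779" = "TCC", "780" = "CCA",
  "781" = "TAT",
  "801" = "TGA")

.randBases <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

#' Build the fixture genome and transcript models
#'
#' Deterministic under `config$seed`: two contigs, a plus-strand transcript
#' (TXA00001.1, 801 codons) carrying the hard-coded edge-case loci and a
#' reference override at c.1621, and a minus-strand transcript (TXB00002.1,
#' 301 codons) with a planted exonic homopolymer.  Planted repeats are
#' recorded in a manifest.
#'
#' @param config a [simulationConfig()].
#' @return list with `genome` ([Biostrings::DNAStringSet]), `transcripts`
#'   (named list of [TranscriptModel]), `manifest` (data.frame) and
#'   `config`.
#' @export
makeFixture <- function(config = simulationConfig()) {
  set.seed(.subSeed(config$seed, 1L))
  sense <- .senseCodons()

  ## --- txA coding sequence: 801 codons -----------------------------------
  nCodons <- 801L
  codons <- sample(sense, nCodons, replace = TRUE)
  codons[as.integer(names(.txaPlanted))] <- unname(.txaPlanted)
  cds <- paste(codons, collapse = "")
  utr5 <- .randBases(60L)
  utr3 <- paste0(strrep("GCT", 21L), "TAA", "CTAGTTAGCTGATAGGTAAT",
                 strrep("GCA", 11L), "G")
  stopifnot(nchar(utr3) == 120L)
  txSeqA <- paste0(utr5, cds, utr3)

  ## --- txA genome layout -------------------------------------------------
  intron1 <- paste0(.randBases(98L), "A", "TTTTT", "C", .randBases(292L),
                    "CAG")
  stopifnot(nchar(intron1) == 400L)
  intron2 <- paste0("GTGAGTGAC", .randBases(90L), "AA", "CTCTCTCT", "G",
                    .randBases(390L))
  stopifnot(nchar(intron2) == 500L)
  exon1 <- substr(txSeqA, 1L, 1259L)
  exon2 <- substr(txSeqA, 1260L, 1955L)
  exon3 <- substr(txSeqA, 1956L, 2583L)
  ctgA <- paste0(.randBases(100L), exon1, intron1, exon2, intron2, exon3,
                 .randBases(117L))
  stopifnot(nchar(ctgA) == 3700L)
  ## reference override: the genome carries A where the transcript has G
  ## (c.1621, genomic 2181)
  gOverride <- 2181L
  substr(ctgA, gOverride, gOverride) <- "A"
  txA <- TranscriptModel("TXA00001", 1L, "GENA", "ctgA", "+",
                         cbind(c(101L, 1760L, 2956L),
                               c(1359L, 2455L, 3583L)),
                         cdsStart = 61L, cdsEnd = 2463L,
                         overrides = data.frame(gpos = gOverride,
                                                base = "G"))

  ## --- txB: minus strand -------------------------------------------------
  codB <- sample(sense, 299L, replace = TRUE)
  codB[99L] <- "CAT"; codB[100L] <- "GGG"; codB[101L] <- "GGA"
  cdsB <- paste0("ATG", paste(codB, collapse = ""), "TGA")
  txSeqB <- paste0(.randBases(30L), cdsB, .randBases(63L))
  stopifnot(nchar(txSeqB) == 996L)
  e1 <- substr(txSeqB, 1L, 400L)
  e2 <- substr(txSeqB, 401L, 700L)
  e3 <- substr(txSeqB, 701L, 996L)
  rc <- function(x) .revComp(x)
  ctgB <- paste0(.randBases(300L), rc(e3), .randBases(180L), rc(e2),
                 .randBases(150L), rc(e1), .randBases(274L))
  stopifnot(nchar(ctgB) == 1900L)
  txB <- TranscriptModel("TXB00002", 1L, "GENB", "ctgB", "-",
                         cbind(c(301L, 777L, 1227L),
                               c(596L, 1076L, 1626L)),
                         cdsStart = 31L, cdsEnd = 933L)

  ## --- txC: large plus-strand transcript for bulk variant placement ------
  codC <- sample(sense, 2999L, replace = TRUE)
  cdsC <- paste0("ATG", paste(codC, collapse = ""), "TGA")
  utr3C <- paste0(strrep("GCT", 9L), "TAA", .randBases(60L))
  txSeqC <- paste0(.randBases(30L), cdsC, utr3C)
  stopifnot(nchar(txSeqC) == 9123L)
  e1C <- substr(txSeqC, 1L, 3000L)
  e2C <- substr(txSeqC, 3001L, 6000L)
  e3C <- substr(txSeqC, 6001L, 9123L)
  ctgC <- paste0(.randBases(200L), e1C, .randBases(200L), e2C,
                 .randBases(250L), e3C, .randBases(227L))
  stopifnot(nchar(ctgC) == 10000L)
  txC <- TranscriptModel("TXC00003", 1L, "GENC", "ctgC", "+",
                         cbind(c(201L, 3401L, 6651L),
                               c(3200L, 6400L, 9773L)),
                         cdsStart = 31L, cdsEnd = 9033L)

  genome <- Biostrings::DNAStringSet(c(ctgA = ctgA, ctgB = ctgB,
                                       ctgC = ctgC))
  transcripts <- list(txA, txB, txC)
  names(transcripts) <- vapply(transcripts, txId, character(1L))

  manifest <- data.frame(
    name = c("cRun", "aRun", "agcTandem", "gtgaDonor", "gJunctionRun",
             "intron1T", "intron2CT", "txbGRun"),
    contig = c(rep("ctgA", 7L), "ctgB"),
    transcript = c(rep(txId(txA), 7L), txId(txB)),
    placement = c("exonic", "exonic", "exonic", "junction", "junction",
                  "intronic", "intronic", "exonic"),
    unit = c("C", "A", "AGC", "GTGA", "G", "T", "CT", "G"),
    copies = c(4L, 6L, 3L, 2L, 3L, 5L, 4L, 5L),
    location = c("c.402-405", "c.423-428", "c.1948-1956",
                 "c.1895+1..+8", "c.1200-1..1201", "intron1:100-104",
                 "intron2:101-108", "c.298-302"),
    stringsAsFactors = FALSE)

  list(genome = genome, transcripts = transcripts, manifest = manifest,
       config = config)
}

## ------------------------------------------------------------------------
## truth set generation
## ------------------------------------------------------------------------

## coding positions to keep variant sampling away from planted loci
.txaExcluded <- function() {
  spans <- rbind(c(1, 9), c(157, 174), c(394, 435), c(916, 957),
                 c(1192, 1209), c(1612, 1632), c(1792, 1806),
                 c(1888, 1902), c(1939, 1965), c(2254, 2284),
                 c(2323, 2346), c(2395, 2403))
  unlist(apply(spans, 1L, function(x) x[1L]:x[2L]))
}

.freeCodingPositions <- function(txLabel, ctx) {
  n <- ctx$cdsEnd - ctx$cdsStart + 1L
  if (startsWith(txLabel, "TXA")) setdiff(10:(n - 12L), .txaExcluded())
  else if (startsWith(txLabel, "TXB")) setdiff(10:(n - 12L), 289:313)
  else 10:(n - 12L)
}

.idxOfCds <- function(ctx, cpos) ctx$idxByTpos[ctx$cdsStart + cpos - 1L]

## VCF-style record for a transcript-space edit; alleles are genome bases.
.vcfForEdit <- function(ctx, genome, kind, s, e = s, insBases = NULL,
                        altBases = NULL) {
  contig <- ctx$tx@contig
  gOf <- function(cpos) ctx$gposOfIdx(.idxOfCds(ctx, cpos))
  orient <- function(b) if (ctx$plus) b else .revComp(b)
  if (kind == "substitution") {
    g <- gOf(s)
    list(contig = contig, pos = g, ref = .gbase(genome, contig, g),
         alt = orient(altBases))
  } else if (kind == "deletion") {
    g <- sort(c(gOf(s), gOf(e)))
    list(contig = contig, pos = g[1L] - 1L,
         ref = .gbase(genome, contig, g[1L] - 1L, g[2L]),
         alt = .gbase(genome, contig, g[1L] - 1L))
  } else if (kind == "insertion") {   # insBases in transcript orientation,
    g <- sort(c(gOf(s), gOf(s + 1L))) # inserted between cds s and s+1
    list(contig = contig, pos = g[1L],
         ref = .gbase(genome, contig, g[1L]),
         alt = paste0(.gbase(genome, contig, g[1L]), orient(insBases)))
  } else if (kind == "delins") {
    g <- sort(c(gOf(s), gOf(e)))
    list(contig = contig, pos = g[1L],
         ref = .gbase(genome, contig, g[1L], g[2L]),
         alt = orient(altBases))
  } else stop("bad kind")
}

#' Generate the truth variant set with canonical annotations
#'
#' Samples variant sites per class from the fixture (deletions are placed in
#' repeat runs so that 3'-shifting is exercised; insertions are re-drawn
#' until they are not duplications), produces the truth VCF rows, and
#' annotates every record with [annotateVariant()] so the truth table
#' carries canonical coding/protein HGVS and effect terms.  A
#' reference-override identity record (c.1621G=) is always included.
#'
#' @param config a [simulationConfig()].
#' @param fixture result of [makeFixture()].
#' @return list with `variants` (truth VCF table; phased MNVs as two rows)
#'   and `records` (truth annotation table: id, alt, transcript,
#'   coding_hgvs, protein_hgvs, effects, type, region).
#' @export
makeTruth <- function(config, fixture) {
  genome <- fixture$genome
  ctxs <- lapply(fixture$transcripts, .txContext, genome = genome)
  cnt <- config$counts
  recs <- list()
  vrows <- list()
  recNo <- 0L

  pickTx <- function(i) {
    ## deterministic split: 25% small plus-strand (planted loci), 10%
    ## minus-strand, 65% large bulk transcript
    m <- i %% 20L
    if (m %in% c(0L, 10L)) names(ctxs)[2L]
    else if (m %in% 1:5) names(ctxs)[1L]
    else names(ctxs)[3L]
  }
  nextId <- function() {
    recNo <<- recNo + 1L
    sprintf("SYNV%06d", recNo)
  }
  emit <- function(id, txLabel, vcf, phase = NA_character_,
                   extraRows = NULL) {
    v <- variantTable(vcf$contig, vcf$pos, vcf$ref, vcf$alt, id = id,
                      phaseGroup = phase)
    if (!is.null(extraRows)) v <- rbind(v, extraRows)
    tx <- fixture$transcripts[[txLabel]]
    mergedV <- mergePhasedMnv(leftAlign(v, genome))
    ann <- annotateVariant(mergedV[1L, ], tx, genome,
                           ctx = ctxs[[txLabel]])
    stopifnot(ann@status == "annotated")
    vrows[[length(vrows) + 1L]] <<- v
    recs[[length(recs) + 1L]] <<- data.frame(
      id = id,
      alt = mergedV$alt[1L],
      transcript = txLabel,
      coding_hgvs = formatPreferred(ann@coding),
      protein_hgvs = if (is.null(ann@protein)) ""
                     else formatPreferred(ann@protein),
      effects = paste(ann@effects, collapse = ","),
      type = variantType(mergedV[1L, , drop = FALSE], genome),
      region = .regionOfChange(ann@coding@change),
      stringsAsFactors = FALSE)
    invisible(NULL)
  }
  drawFrom <- function(i, pool, n = 1L, replace = FALSE) {
    set.seed(.subSeed(config$seed, 7919 * as.numeric(i) + recNo))
    if (length(pool) == 1L && n == 1L) return(pool)
    sample(pool, n, replace = replace)
  }
  ## genomic positions already used by earlier records (one-base margin);
  ## keeping records disjoint prevents de-duplication collisions and keeps
  ## phased-MNV merging unambiguous
  used <- list()
  clash <- function(vcf) {
    span <- (vcf$pos - 1L):(vcf$pos + nchar(vcf$ref))
    any(span %in% used[[vcf$contig]])
  }
  markUsed <- function(vcf) {
    span <- (vcf$pos - 1L):(vcf$pos + nchar(vcf$ref))
    used[[vcf$contig]] <<- c(used[[vcf$contig]], span)
  }

  ## --- plain SNVs ---------------------------------------------------------
  for (i in seq_len(cnt[["snv"]])) {
    txLabel <- pickTx(i)
    ctx <- ctxs[[txLabel]]
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > 5000L) stop("unsatisfiable placement: variant pool exhausted")
      cpos <- drawFrom(i + 1000L * tries, .freeCodingPositions(txLabel, ctx))
      refT <- ctx$base[.idxOfCds(ctx, cpos)]
      altT <- drawFrom(i + 1000L * tries + 1L,
                       setdiff(c("A", "C", "G", "T"), refT))
      ## avoid accidental nonsense (counted separately)
      cod <- (cpos - 1L) %/% 3L + 1L
      tri <- substr(ctx$cdsSeq, cod * 3L - 2L, cod * 3L)
      posIn <- cpos - (cod * 3L - 3L)
      substr(tri, posIn, posIn) <- altT
      if (.translateNt(tri) == "*") next
      vcfRow <- .vcfForEdit(ctx, genome, "substitution", cpos,
                            altBases = altT)
      if (!clash(vcfRow)) break
    }
    markUsed(vcfRow)
    emit(nextId(), txLabel, vcfRow)
  }

  ## --- nonsense SNVs (star-for-Ter targets) -------------------------------
  for (i in seq_len(cnt[["nonsense"]])) {
    txLabel <- pickTx(i)
    ctx <- ctxs[[txLabel]]
    free <- .freeCodingPositions(txLabel, ctx)
    cand <- NULL
    tries <- 0L
    while (is.null(cand) && tries < 500L) {
      tries <- tries + 1L
      if (tries > 5000L) stop("unsatisfiable placement: variant pool exhausted")
      cpos <- drawFrom(i * 13L + tries, free)
      cod <- (cpos - 1L) %/% 3L + 1L
      tri <- substr(ctx$cdsSeq, cod * 3L - 2L, cod * 3L)
      posIn <- cpos - (cod * 3L - 3L)
      for (b in c("A", "G", "T")) {
        tri2 <- tri
        substr(tri2, posIn, posIn) <- b
        if (b != substr(tri, posIn, posIn) && .translateNt(tri2) == "*") {
          cand <- list(cpos = cpos, alt = b)
          break
        }
      }
      if (!is.null(cand)) {
        vcfRow <- .vcfForEdit(ctx, genome, "substitution", cand$cpos,
                              altBases = cand$alt)
        if (clash(vcfRow)) cand <- NULL
      }
    }
    if (is.null(cand)) stop("could not place a nonsense SNV")
    markUsed(vcfRow)
    emit(nextId(), txLabel, vcfRow)
  }

  ## --- deletions in repeat runs (shiftable) -------------------------------
  for (i in seq_len(cnt[["deletion"]])) {
    txLabel <- pickTx(i)
    ctx <- ctxs[[txLabel]]
    free <- .freeCodingPositions(txLabel, ctx)
    runPos <- free[vapply(free, function(p) {
      i1 <- .idxOfCds(ctx, p); i2 <- .idxOfCds(ctx, p + 1L)
      i2 == i1 + 1L && ctx$base[i1] == ctx$base[i2]
    }, logical(1L))]
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > 5000L) stop("unsatisfiable placement: variant pool exhausted")
      cpos <- drawFrom(i * 17L + 1000L * tries, runPos)
      vcfRow <- .vcfForEdit(ctx, genome, "deletion", cpos)
      if (!clash(vcfRow)) break
    }
    markUsed(vcfRow)
    emit(nextId(), txLabel, vcfRow)
  }

  ## --- duplications (multi-base) ------------------------------------------
  for (i in seq_len(cnt[["duplication"]])) {
    txLabel <- pickTx(i)
    ctx <- ctxs[[txLabel]]
    free <- .freeCodingPositions(txLabel, ctx)
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > 5000L) stop("unsatisfiable placement: variant pool exhausted")
      u <- drawFrom(i * 19L + 1000L * tries, 1:6)
      p <- drawFrom(i * 19L + 1000L * tries + 1L, free)
      idx <- vapply((p - u + 1L):(p + 1L), function(cp)
        .idxOfCds(ctx, cp), integer(1L))
      if (any(diff(idx) != 1L)) next    # unit and flank within one exon
      unit <- paste(ctx$base[idx[seq_len(u)]], collapse = "")
      vcfRow <- .vcfForEdit(ctx, genome, "insertion", p, insBases = unit)
      if (!clash(vcfRow)) break
    }
    markUsed(vcfRow)
    emit(nextId(), txLabel, vcfRow)
  }

  ## --- plain insertions (not duplications) --------------------------------
  for (i in seq_len(cnt[["insertion"]])) {
    txLabel <- pickTx(i)
    ctx <- ctxs[[txLabel]]
    free <- .freeCodingPositions(txLabel, ctx)
    tx <- fixture$transcripts[[txLabel]]
    ok <- FALSE
    for (tries in 1:200) {
      p <- drawFrom(i * 23L + tries, free)
      len <- drawFrom(i * 23L + tries + 1L, 2:6)
      ins <- paste(drawFrom(i * 23L + tries + 2L,
                            c("A", "C", "G", "T"), n = len,
                            replace = TRUE),
                   collapse = "")
      if (.idxOfCds(ctx, p + 1L) != .idxOfCds(ctx, p) + 1L) next
      ch <- new("CodingChange", kind = "insertion",
                start = CdsCoord(p), end = CdsCoord(p + 1L),
                altBases = ins)
      if (.shiftCoding(ch, ctx)@kind != "insertion") next
      vcfRow <- .vcfForEdit(ctx, genome, "insertion", p, insBases = ins)
      if (!clash(vcfRow)) { ok <- TRUE; break }
    }
    if (!ok) stop("could not place a non-duplication insertion")
    markUsed(vcfRow)
    emit(nextId(), txLabel, vcfRow)
  }

  ## --- delins -------------------------------------------------------------
  for (i in seq_len(cnt[["delins"]])) {
    txLabel <- pickTx(i)
    ctx <- ctxs[[txLabel]]
    free <- .freeCodingPositions(txLabel, ctx)
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > 5000L) stop("unsatisfiable placement: variant pool exhausted")
      s <- drawFrom(i * 29L + 1000L * tries, free)
      w <- drawFrom(i * 29L + 1000L * tries + 1L, 2:4)
      aw <- drawFrom(i * 29L + 1000L * tries + 2L, 2:4)
      idx <- vapply(s:(s + w - 1L), function(cp) .idxOfCds(ctx, cp),
                    integer(1L))
      if (any(diff(idx) != 1L)) next
      ref <- paste(ctx$base[idx], collapse = "")
      alt <- paste(drawFrom(i * 29L + 1000L * tries + 3L,
                            c("A", "C", "G", "T"), n = aw,
                            replace = TRUE),
                   collapse = "")
      if (substr(alt, 1L, 1L) == substr(ref, 1L, 1L) ||
          substr(alt, aw, aw) == substr(ref, w, w)) next
      vcfRow <- .vcfForEdit(ctx, genome, "delins", s, s + w - 1L,
                            altBases = alt)
      if (!clash(vcfRow)) break
    }
    markUsed(vcfRow)
    emit(nextId(), txLabel, vcfRow)
  }

  ## --- phased MNVs --------------------------------------------------------
  for (i in seq_len(cnt[["mnv"]])) {
    txLabel <- pickTx(i)
    ctx <- ctxs[[txLabel]]
    free <- .freeCodingPositions(txLabel, ctx)
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > 5000L) stop("unsatisfiable placement: variant pool exhausted")
      p <- drawFrom(i * 31L + 1000L * tries, free)
      if (.idxOfCds(ctx, p + 1L) != .idxOfCds(ctx, p) + 1L) next
      alts <- vapply(c(p, p + 1L), function(cp) {
        refT <- ctx$base[.idxOfCds(ctx, cp)]
        drawFrom(i * 31L + 1000L * tries + cp,
                 setdiff(c("A", "C", "G", "T"), refT))
      }, character(1L))
      v1 <- .vcfForEdit(ctx, genome, "substitution", p,
                        altBases = alts[1L])
      v2 <- .vcfForEdit(ctx, genome, "substitution", p + 1L,
                        altBases = alts[2L])
      if (!clash(v1) && !clash(v2)) break
    }
    markUsed(v1); markUsed(v2)
    id <- nextId()
    extra <- variantTable(v2$contig, v2$pos, v2$ref, v2$alt, id = id,
                          phaseGroup = paste0("PG", i))
    emit(id, txLabel, v1, phase = paste0("PG", i), extraRows = extra)
  }

  ## --- intronic / splice --------------------------------------------------
  for (i in seq_len(cnt[["intronic"]])) {
    txLabel <- pickTx(i)
    ctx <- ctxs[[txLabel]]
    intronIdx <- which(ctx$region < 0L)
    ## stay clear of the planted donor/acceptor contexts on txA
    if (startsWith(txLabel, "TXA"))
      intronIdx <- intronIdx[!(intronIdx %in%
        c(which(ctx$region == -2L)[1:12],
          utils::tail(which(ctx$region == -1L), 6L),
          which(ctx$region == -1L)[98:105]))]
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > 5000L) stop("unsatisfiable placement: variant pool exhausted")
      set.seed(.subSeed(config$seed,
                        7919 * (as.numeric(i) * 37 + tries) + recNo))
      idx <- sample(intronIdx, 1L)
      g <- ctx$gposOfIdx(idx)
      refG <- .gbase(genome, ctx$tx@contig, g)
      altG <- sample(setdiff(c("A", "C", "G", "T"), refG), 1L)
      vcfRow <- list(contig = ctx$tx@contig, pos = g, ref = refG,
                     alt = altG)
      if (!clash(vcfRow)) break
    }
    markUsed(vcfRow)
    emit(nextId(), txLabel, vcfRow)
  }

  ## --- UTR ----------------------------------------------------------------
  for (i in seq_len(cnt[["utr"]])) {
    txLabel <- pickTx(i)
    ctx <- ctxs[[txLabel]]
    utrT <- c(5:(ctx$cdsStart - 5L),
              (ctx$cdsEnd + 4L):(ctx$txLen - 4L))
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > 5000L) stop("unsatisfiable placement: variant pool exhausted")
      set.seed(.subSeed(config$seed,
                        7919 * (as.numeric(i) * 41 + tries) + recNo))
      tp <- sample(utrT, 1L)
      idx <- ctx$idxByTpos[tp]
      g <- ctx$gposOfIdx(idx)
      refG <- .gbase(genome, ctx$tx@contig, g)
      altG <- sample(setdiff(c("A", "C", "G", "T"), refG), 1L)
      vcfRow <- list(contig = ctx$tx@contig, pos = g, ref = refG,
                     alt = altG)
      if (!clash(vcfRow)) break
    }
    markUsed(vcfRow)
    emit(nextId(), txLabel, vcfRow)
  }

  ## --- the reference-override identity record -----------------------------
  ctxA <- ctxs[[1L]]
  gOv <- fixture$transcripts[[1L]]@overrides$gpos[1L]
  emit(nextId(), names(ctxs)[1L],
       list(contig = "ctgA", pos = gOv,
            ref = .gbase(genome, "ctgA", gOv),
            alt = fixture$transcripts[[1L]]@overrides$base[1L]))

  records <- do.call(rbind, recs)
  variants <- do.call(rbind, vrows)
  rownames(records) <- rownames(variants) <- NULL
  list(variants = variants, records = records)
}

.regionOfChange <- function(ch) {
  offs <- c(ch@start@offset, ch@end@offset)
  stars <- c(ch@start@star, ch@end@star)
  anchors <- c(ch@start@anchor, ch@end@anchor)
  if (all(offs != 0L)) "intronic"
  else if (any(offs != 0L)) "junction"
  else if (any(stars) || any(anchors < 0L)) "utr"
  else "exonic"
}

## ------------------------------------------------------------------------
## corruption
## ------------------------------------------------------------------------

.formatProteinOneLetter <- function(pch) {
  a1 <- function(r) residueConvert(r, "one")
  p1 <- paste0(a1(pch@startRes), pch@startPos)
  iv <- if (!is.na(pch@endPos) && pch@endPos != pch@startPos)
    paste0(p1, "_", a1(pch@endRes), pch@endPos) else p1
  alt <- paste(vapply(pch@altRes, a1, character(1L)), collapse = "")
  switch(pch@kind,
    identity = "p.=",
    synonymous = paste0("p.", p1, a1(pch@startRes)),
    substitution = paste0("p.", p1, alt),
    deletion = paste0("p.", iv, "del"),
    duplication = paste0("p.", iv, "dup"),
    insertion = paste0("p.", iv, "ins", alt),
    delins = paste0("p.", iv, "delins", alt),
    frameshift = if (!is.na(pch@fsNewStop))
      paste0("p.", p1, "fs*", pch@fsNewStop) else paste0("p.", p1, "fs"),
    extension = paste0("p.*", pch@startPos, alt),
    paste0("p.", p1))
}

#' Corrupt a truth annotation table with labelled error modes
#'
#' Each record is hit independently by each mode with its configured rate
#' (per-record sub-seeds derived from `seed`); the label table records
#' exactly which modes fired per record, and inapplicable modes are skipped
#' and logged.  Modes: `no-right-shift` (deletions re-expressed at their
#' 5'-most position), `over-shift-11` (anchors displaced 11 bases),
#' `dup-as-ins` (multi-base duplications written as insertions after the
#' unit), `ins-as-dup-redundant-delins` (single-base duplications written
#' as redundant delins), `indel-as-substitution-dialect`,
#' `missing-del-designator`, `fs-short-form`, `one-letter-protein`,
#' `star-for-Ter`, `version-bump` (provokes not_assessed), and
#' `protein-for-intronic` (fabricated protein syntax on intronic/UTR
#' records).
#'
#' @param truth truth records from [makeTruth()].
#' @param fixture result of [makeFixture()].
#' @param rates named list of per-mode rates (defaults from the config).
#' @param seed corruption seed.
#' @return list with `records` (corrupted table), `labels` (id, mode) and
#'   `skipped` (id, mode, reason).
#' @export
corruptAnnotations <- function(truth, fixture,
                               rates = fixture$config$rates,
                               seed = fixture$config$seed) {
  records <- truth
  labels <- list()
  skipped <- list()
  genome <- fixture$genome
  ctxCache <- new.env(parent = emptyenv())
  getCtx <- function(txLabel) {
    if (is.null(ctxCache[[txLabel]]))
      ctxCache[[txLabel]] <- .txContext(fixture$transcripts[[txLabel]],
                                        genome)
    ctxCache[[txLabel]]
  }
  fire <- function(i, m, rate) {
    set.seed(.subSeed(seed, as.numeric(i) * 101 + m * 13))
    stats::runif(1L) < rate
  }
  fmtC <- function(ch) paste0("c.", .formatCodingChange(ch))

  for (i in seq_len(nrow(records))) {
    txLabel0 <- records$transcript[i]
    for (m in seq_along(.errorModes)) {
      mode <- .errorModes[m]
      rate <- rates[[mode]]
      if (is.null(rate) || rate <= 0) next
      if (!fire(i, m, rate)) next
      ctext <- records$coding_hgvs[i]
      ptext <- records$protein_hgvs[i]
      cexpr <- tryCatch(parseCoding(ctext),
                        hgvsParseError = function(e) NULL)
      ch <- if (!is.null(cexpr)) cexpr@change else NULL
      pexpr <- if (nzchar(ptext))
        tryCatch(parseProtein(ptext), hgvsParseError = function(e) NULL)
      else NULL
      pch <- if (!is.null(pexpr)) pexpr@change else NULL
      tx <- fixture$transcripts[[txLabel0]]
      ctx <- getCtx(txLabel0)
      skip <- function(reason) {
        skipped[[length(skipped) + 1L]] <<-
          data.frame(id = records$id[i], mode = mode, reason = reason)
      }
      label <- function() {
        labels[[length(labels) + 1L]] <<-
          data.frame(id = records$id[i], mode = mode)
      }
      applied <- FALSE
      if (mode == "no-right-shift") {
        if (is.null(ch) || ch@kind != "deletion") { skip("not-a-deletion"); next }
        ch5 <- .shiftCoding(ch, ctx, dir = 5L)
        t5 <- fmtC(ch5)
        if (identical(t5, ctext)) { skip("not-shiftable"); next }
        records$coding_hgvs[i] <- t5
        applied <- TRUE
      } else if (mode == "over-shift-11") {
        if (is.null(ch) ||
            !ch@kind %in% c("deletion", "insertion", "duplication")) {
          skip("not-an-indel"); next
        }
        ch@start <- .coordAdd(ch@start, 11L)
        ch@end <- .coordAdd(ch@end, 11L)
        records$coding_hgvs[i] <- fmtC(ch)
        applied <- TRUE
      } else if (mode == "dup-as-ins") {
        if (is.null(ch) || ch@kind != "duplication" || .width1(ch)) {
          skip("not-a-multibase-dup"); next
        }
        s <- .idxOfCoord(ctx, ch@start, ctx$cdsStart, ctx$cdsEnd)
        e <- .idxOfCoord(ctx, ch@end, ctx$cdsStart, ctx$cdsEnd)
        unit <- paste(ctx$base[s:e], collapse = "")
        insCh <- new("CodingChange", kind = "insertion", start = ch@end,
                     end = .coordAdd(ch@end, 1L), altBases = unit)
        records$coding_hgvs[i] <- fmtC(insCh)
        applied <- TRUE
      } else if (mode == "ins-as-dup-redundant-delins") {
        if (is.null(ch) || ch@kind != "duplication" || !.width1(ch)) {
          skip("not-a-1bp-dup"); next
        }
        p <- .idxOfCoord(ctx, ch@start, ctx$cdsStart, ctx$cdsEnd)
        X <- ctx$base[p]
        B <- ctx$base[p - 1L]
        prev <- .coordOfIdx(ctx, p - 1L, ctx$cdsStart, ctx$cdsEnd)
        records$coding_hgvs[i] <-
          paste0("c.", formatCdsCoord(prev), "del", B, "ins", B, X)
        applied <- TRUE
      } else if (mode == "indel-as-substitution-dialect") {
        if (is.null(ch) || ch@kind != "delins") { skip("not-a-delins"); next }
        s <- .idxOfCoord(ctx, ch@start, ctx$cdsStart, ctx$cdsEnd)
        e <- .idxOfCoord(ctx, ch@end, ctx$cdsStart, ctx$cdsEnd)
        R <- paste(ctx$base[s:e], collapse = "")
        iv <- if (s == e) formatCdsCoord(ch@start)
              else paste0(formatCdsCoord(ch@start), "_",
                          formatCdsCoord(ch@end))
        records$coding_hgvs[i] <- paste0("c.", iv, R, ">", ch@altBases)
        applied <- TRUE
      } else if (mode == "missing-del-designator") {
        if (is.null(ch) || ch@kind != "deletion") { skip("not-a-deletion"); next }
        s <- .idxOfCoord(ctx, ch@start, ctx$cdsStart, ctx$cdsEnd)
        e <- .idxOfCoord(ctx, ch@end, ctx$cdsStart, ctx$cdsEnd)
        D <- paste(ctx$base[s:e], collapse = "")
        P <- ctx$base[s - 1L]
        prev <- .coordOfIdx(ctx, s - 1L, ctx$cdsStart, ctx$cdsEnd)
        records$coding_hgvs[i] <-
          paste0("c.", formatCdsCoord(prev), P, D, ">", P)
        applied <- TRUE
      } else if (mode == "fs-short-form") {
        if (is.null(pch) || pch@kind != "frameshift" ||
            is.na(pch@fsNewStop)) { skip("not-a-long-fs"); next }
        records$protein_hgvs[i] <- paste0("p.", pch@startRes, pch@startPos,
                                          "fs")
        applied <- TRUE
      } else if (mode == "one-letter-protein") {
        if (is.null(pch)) { skip("no-protein"); next }
        records$protein_hgvs[i] <- .formatProteinOneLetter(pch)
        applied <- TRUE
      } else if (mode == "star-for-Ter") {
        if (is.null(pch) || pch@kind != "substitution" ||
            !length(pch@altRes) || pch@altRes[1L] != "Ter") {
          skip("not-a-nonsense"); next
        }
        records$protein_hgvs[i] <- paste0("p.", pch@startRes, pch@startPos,
                                          "*")
        applied <- TRUE
      } else if (mode == "version-bump") {
        acc <- .splitAccession(paste0(txLabel0, ":x"))
        records$transcript[i] <- paste0(acc$accession, ".",
                                        acc$version + 1L)
        applied <- TRUE
      } else if (mode == "protein-for-intronic") {
        if (nzchar(ptext) ||
            !grepl("intron|UTR|splice", records$effects[i])) {
          skip("not-intronic"); next
        }
        records$protein_hgvs[i] <- "p.Arg100Trp"
        applied <- TRUE
      }
      if (applied) label()
    }
  }
  list(records = records,
       labels = if (length(labels)) do.call(rbind, labels) else
         data.frame(id = character(), mode = character()),
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(id = character(), mode = character(),
                    reason = character()))
}

## ------------------------------------------------------------------------
## bundle output
## ------------------------------------------------------------------------

#' Write a fixture bundle to disk
#'
#' FASTA genome, GFF3 transcripts, truth VCF, truth annotation TSV and a
#' JSON manifest.  Byte-identical across runs with the same configuration.
#'
#' @param fixture result of [makeFixture()].
#' @param truth result of [makeTruth()].
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths.
#' @export
writeFixtureBundle <- function(fixture, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "transcripts.gff3")
  vcf <- file.path(dir, "truth.vcf")
  tsv <- file.path(dir, "truth.tsv")
  mf <- file.path(dir, "manifest.json")
  writeGenome(fixture$genome, fa)
  writeTranscriptsGff3(fixture$transcripts, gff)
  writeVcfVariants(truth$variants, vcf, fixture$genome)
  writeAnnotationTable(truth$records, tsv)
  jsonlite::write_json(list(seed = fixture$config$seed,
                            manifest = fixture$manifest),
                       mf, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(c(fa, gff, vcf, tsv, mf))
}

#' Write an annotation table as TSV
#' @param records annotation records (truth or corrupted layout).
#' @param path output TSV.
#' @export
writeAnnotationTable <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
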