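test_that("fixtures are deterministic under a seed", {
  f1 <- makeFixture(simulationConfig(seed = 33))
  f2 <- makeFixture(simulationConfig(seed = 33))
  expect_identical(as.character(f1$genome), as.character(f2$genome))
  expect_identical(f1$manifest, f2$manifest)
  f3 <- makeFixture(simulationConfig(seed = 34))
  expect_false(identical(as.character(f1$genome), as.character(f3$genome)))
})

test_that("the manifest reflects the planted repeats, including junctions", {
  fx <- sharedFixture()
  g <- fx$genome; txA <- sharedTxA()
  cds <- cdsSequence(txA, g)
  expect_equal(substr(cds, 402, 405), "CCCC")          # cRun
  expect_equal(substr(cds, 423, 428), "AAAAAA")        # aRun
  expect_equal(substr(cds, 1948, 1956), "AGCAGCAGC")   # agcTandem
  ## donor GTGA tandem truly sits at the start of intron 2 in the FASTA
  gI2 <- cdnaToGenomic(txA, CdsCoord(1895L)) + 1L
  expect_equal(as.character(Biostrings::subseq(g[["ctgA"]], gI2, gI2 + 8L)),
               "GTGAGTGAC")
  ## acceptor G run straddles the intron1/exon2 boundary
  gAcc <- cdnaToGenomic(txA, CdsCoord(1200L, offset = -1L))
  expect_equal(as.character(Biostrings::subseq(g[["ctgA"]], gAcc, gAcc + 2L)),
               "GGG")
  expect_true(all(c("gtgaDonor", "gJunctionRun") %in% fx$manifest$name))
  expect_true(all(fx$manifest$placement %in%
                    c("exonic", "intronic", "junction")))
})

test_that("truth sets cover the configured classes with canonical annotations", {
  tr <- sharedTruth()
  cfg <- simulationConfig(seed = 1)
  expect_equal(nrow(tr$records), sum(cfg$counts) + 1L)  # + override record
  expect_true(all(c("deletion", "duplication", "insertion", "SNV") %in%
                    tr$records$type))
  expect_equal(sum(tr$records$region == "intronic"),
               cfg$counts[["intronic"]])
  ## every deletion is 3'-shifted in truth: shifting again is a no-op
  fx <- sharedFixture()
  dels <- tr$records[tr$records$type == "deletion", ]
  for (k in seq_len(nrow(dels))) {
    tx <- fx$transcripts[[dels$transcript[k]]]
    ch <- parseCoding(dels$coding_hgvs[k])@change
    expect_equal(
      hgvsConcord:::.formatCodingChange(shift3Coding(ch, tx, fx$genome)),
      hgvsConcord:::.formatCodingChange(ch))
  }
  ## truth VCF round-trips through the writer/reader
  d <- withr::local_tempdir()
  suppressWarnings(writeFixtureBundle(fx, tr, d))
  v2 <- readVcfVariants(file.path(d, "truth.vcf"))
  expect_equal(nrow(v2), nrow(tr$variants))
  expect_identical(v2$alt, tr$variants$alt)
})

test_that("spot check: a planted truth record agrees with the sequence oracle", {
  fx <- sharedFixture()
  tr <- sharedTruth()
  dels <- which(tr$records$type == "deletion" &
                  startsWith(tr$records$transcript, "TXA"))
  k <- dels[1]
  id <- tr$records$id[k]
  v <- tr$variants[tr$variants$id == id, ]
  tx <- fx$transcripts[[tr$records$transcript[k]]]
  ## applying the truth coding change to the transcript equals applying the
  ## VCF record to the genome and re-splicing
  ch <- parseCoding(tr$records$coding_hgvs[k])@change
  viaHgvs <- applyCodingChange(ch, tx, fx$genome)
  s <- as.character(fx$genome[["ctgA"]])
  sMut <- applyVcfEdit(s, v$pos, v$ref, v$alt)
  gMut <- fx$genome
  ## deletion shrinks the contig: rebuild transcript sequence over edited
  ## genome by shifting downstream exon coordinates
  shift <- nchar(v$alt) - nchar(v$ref)
  ex <- as.data.frame(tx@exons)[, c("start", "end")]
  ex$start <- ifelse(ex$start > v$pos, ex$start + shift, ex$start)
  ex$end <- ifelse(ex$end > v$pos, ex$end + shift, ex$end)
  ov <- tx@overrides
  ov$gpos <- ifelse(ov$gpos > v$pos, ov$gpos + shift, ov$gpos)
  tx2 <- TranscriptModel(tx@accession, tx@version, tx@gene, tx@contig,
                         tx@strand, ex, tx@cdsStart, tx@cdsEnd,
                         overrides = ov)
  gMut <- Biostrings::DNAStringSet(c(ctgA = sMut,
                                     as.character(fx$genome)[-1]))
  names(gMut) <- names(fx$genome)
  viaVcf <- txSequence(tx2, gMut)
  expect_identical(viaHgvs, viaVcf)
})

test_that("corruption respects rates, applicability and labels", {
  fx <- sharedFixture()
  tr <- sharedTruth()
  ## rate 0 for all modes: corrupted == truth
  co0 <- corruptAnnotations(tr$records, fx,
                            rates = list("star-for-Ter" = 0), seed = 5)
  expect_identical(co0$records, tr$records)
  expect_equal(nrow(co0$labels), 0L)
  ## rate 1 for star-for-Ter: every nonsense record reads "*"
  co1 <- corruptAnnotations(tr$records, fx,
                            rates = list("star-for-Ter" = 1), seed = 5)
  nonsense <- grepl("Ter$", tr$records$protein_hgvs) &
    vapply(tr$records$protein_hgvs, function(p)
      nzchar(p) && parseProtein(p)@change@kind == "substitution",
      logical(1))
  expect_true(all(grepl("\\*$", co1$records$protein_hgvs[nonsense])))
  expect_equal(sort(co1$labels$id), sort(tr$records$id[nonsense]))
  ## inapplicable modes are skipped and logged
  coSkip <- corruptAnnotations(tr$records[tr$records$type == "SNV", ], fx,
                               rates = list("dup-as-ins" = 1), seed = 5)
  expect_equal(nrow(coSkip$labels), 0L)
  expect_gt(nrow(coSkip$skipped), 0L)
})

test_that("corruption classes map to their designed verdict classes at rate 1", {
  fx <- sharedFixture()
  tr <- sharedTruth()
  expectClass <- list(
    "no-right-shift" = "incorrect",
    "dup-as-ins" = "incorrect",
    "protein-for-intronic" = "incorrect",
    "fs-short-form" = "equivalent",
    "star-for-Ter" = "equivalent",
    "ins-as-dup-redundant-delins" = "equivalent",
    "version-bump" = "not_assessed")
  protModes <- c("fs-short-form", "star-for-Ter", "protein-for-intronic")
  for (mode in names(expectClass)) {
    rates <- stats::setNames(list(1), mode)
    co <- corruptAnnotations(tr$records, fx, rates = rates, seed = 8)
    expect_gt(nrow(co$labels), 0)
    res <- evaluateConcordance(co$records, fx$transcripts, fx$genome,
                               reference = tr$records, mode = "compare")
    v <- res$verdicts
    lvl <- if (mode %in% protModes) "protein"
           else if (mode == "version-bump") c("coding", "protein")
           else "coding"
    hit <- v$id %in% co$labels$id & v$level %in% lvl
    expect_true(all(v$status[hit] == expectClass[[mode]]), info = mode)
  }
})

test_that("fixture bundles are byte-identical across runs with one seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    cfg <- simulationConfig(seed = 12)
    fx <- makeFixture(cfg)
    tr <- makeTruth(cfg, fx)
    suppressWarnings(writeFixtureBundle(fx, tr, d))
  }
  for (f in c("genome.fa", "transcripts.gff3", "truth.vcf", "truth.tsv",
              "manifest.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
})
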