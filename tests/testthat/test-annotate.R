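annA <- function(pos, ref, alt) {
  annotateVariant(list(contig = "ctgA", pos = pos, ref = ref, alt = alt),
                  sharedTxA(), sharedGenome())
}
gOfA <- function(cpos, ...) cdnaToGenomic(sharedTxA(), CdsCoord(cpos, ...))
gbA <- function(p) as.character(Biostrings::subseq(sharedGenome()[["ctgA"]],
                                                   p, p))

test_that("missense, MNV-block and phased-pair consequences are called", {
  p1799 <- gOfA(1799L)
  a <- annA(p1799, "T", "A")
  expect_equal(formatPreferred(a@coding), "TXA00001.1:c.1799T>A")
  expect_equal(formatPreferred(a@protein), "TXA00001.1:p.Val600Glu")
  expect_equal(a@effects, "missense_variant")
  ## merged block TG>AT
  a <- annA(p1799, "TG", "AT")
  expect_equal(formatPreferred(a@protein), "TXA00001.1:p.Val600Asp")
  ## merged block GT>AA one base left
  a <- annA(p1799 - 1L, "GT", "AA")
  expect_equal(formatPreferred(a@protein), "TXA00001.1:p.Val600Lys")
})

test_that("a deletion creating an immediate stop is a nonsense call, not fs", {
  p163 <- gOfA(163L)
  a <- annA(p163 - 1L, paste0(gbA(p163 - 1L), gbA(p163)), gbA(p163 - 1L))
  expect_equal(formatPreferred(a@protein), "TXA00001.1:p.Ile55Ter")
  expect_equal(a@effects, "stop_gained")
})

test_that("intronic and UTR variants carry no protein annotation", {
  p <- gOfA(1895L, offset = 5L)
  a <- annA(p, gbA(p), setdiff(c("A", "C", "G", "T"), gbA(p))[1])
  expect_null(a@protein)
  expect_setequal(a@effects, c("splice_region_variant", "intron_variant"))
  ## acceptor -1 deletion: both splice_acceptor and intron terms
  pAcc <- gOfA(1200L, offset = -1L)
  a <- annA(pAcc - 1L, paste0(gbA(pAcc - 1L), gbA(pAcc)), gbA(pAcc - 1L))
  expect_null(a@protein)
  expect_setequal(a@effects, c("splice_acceptor_variant", "intron_variant"))
  ## UTR substitution 4 bases past the stop
  pU <- cdnaToGenomic(sharedTxA(), CdsCoord(4L, star = TRUE))
  a <- annA(pU, gbA(pU), setdiff(c("A", "C", "G", "T"), gbA(pU))[1])
  expect_null(a@protein)
  expect_equal(a@effects, "3_prime_UTR_variant")
})

test_that("a variant matching a transcript override is an identity", {
  a <- annA(2181L, "A", "G")
  expect_true(a@refDifference)
  expect_equal(formatPreferred(a@coding), "TXA00001.1:c.1621G=")
  expect_null(a@protein)
  expect_equal(a@effects, "no_sequence_alteration")
})

test_that("variants outside the locus are not assessed", {
  a <- annA(10L, gbA(10L), setdiff(c("A", "C", "G", "T"), gbA(10L))[1])
  expect_equal(a@status, "not_assessed")
  expect_null(a@coding)
})

test_that("stop-codon events: retained, extension, and residue-level dup", {
  p2402 <- gOfA(2402L)
  a <- annA(p2402, gbA(p2402), "A")
  expect_equal(formatPreferred(a@protein), "TXA00001.1:p.Ter801=")
  expect_equal(a@effects, "stop_retained_variant")
  p2403 <- gOfA(2403L)
  a <- annA(p2403, gbA(p2403), "G")
  expect_equal(formatPreferred(a@protein), "TXA00001.1:p.Ter801TrpextTer22")
  expect_equal(a@effects, "stop_lost")
  ## in-frame 9-bp dup of Gly-Ser-Pro context: residue-level duplication
  p2339 <- gOfA(2339L)
  a <- annA(p2339, gbA(p2339), paste0(gbA(p2339), "GGGCTCCCC"))
  expect_equal(formatPreferred(a@coding), "TXA00001.1:c.2331_2339dup")
  expect_equal(formatPreferred(a@protein), "TXA00001.1:p.Gly778_Pro780dup")
})

test_that("translateConsequence handles delins spanning codons as one event", {
  cds <- cdsSequence(sharedTxA(), sharedGenome())
  ## replace two codons' middle bases so Asp-Ala style MNV -> delins form
  ch <- parseCoding("c.1798_1800delinsTAA")@change
  p <- translateConsequence(ch, cds)
  expect_equal(p@kind, "substitution")   # immediate stop at codon 600
  expect_equal(p@altRes, "Ter")
})

test_that("frameshift long form reports the first changed residue and stop", {
  cds <- cdsSequence(sharedTxA(), sharedGenome())
  ch <- parseCoding("c.700_701insT")@change
  p <- translateConsequence(ch, cds, "")
  expect_equal(p@kind, "frameshift")
  expect_false(is.na(p@fsNewStop))
  expect_error(translateConsequence(ch, substr(cds, 1, 100)),
               "divisible")
})

test_that("protein calls agree with direct translation of the edited CDS", {
  ## independent oracle: reconstruct the mutant protein from the
  ## ProteinChange and compare with translation of the edited sequence
  fx <- sharedFixture()
  g <- fx$genome
  txC <- fx$transcripts[["TXC00003.1"]]
  cds <- cdsSequence(txC, g)
  utr3 <- substr(txSequence(txC, g), nchar(cds) + 31L, 1e7)
  refP <- hgvsConcord:::.translateNt(cds)
  nAA <- nchar(refP)
  set.seed(1234)
  nOk <- 0L
  for (rep in 1:400) {
    p <- sample(10:(nchar(cds) - 30L), 1)
    kind <- sample(c("substitution", "deletion", "insertion", "delins"), 1)
    ch <- switch(kind,
      substitution = {
        refb <- substr(cds, p, p)
        new("CodingChange", kind = "substitution", start = CdsCoord(p),
            end = CdsCoord(p), refBases = refb,
            altBases = sample(setdiff(c("A", "C", "G", "T"), refb), 1))
      },
      deletion = {
        w <- sample(1:6, 1)
        new("CodingChange", kind = "deletion", start = CdsCoord(p),
            end = CdsCoord(p + w - 1L), refBases = substr(cds, p, p + w - 1L))
      },
      insertion = new("CodingChange", kind = "insertion",
                      start = CdsCoord(p), end = CdsCoord(p + 1L),
                      altBases = paste(sample(c("A", "C", "G", "T"),
                                              sample(1:6, 1), TRUE),
                                       collapse = "")),
      delins = {
        w <- sample(1:4, 1)
        new("CodingChange", kind = "delins", start = CdsCoord(p),
            end = CdsCoord(p + w - 1L),
            refBases = substr(cds, p, p + w - 1L),
            altBases = paste(sample(c("A", "C", "G", "T"),
                                    sample(1:4, 1), TRUE), collapse = ""))
      })
    pc <- translateConsequence(ch, cds, utr3)
    ## direct translation of the edited sequence
    varNt <- applyCodingChange(ch, txC, g)
    varNt <- substr(varNt, 31L, nchar(varNt))
    varP <- hgvsConcord:::.translateNt(varNt)
    stopAt <- regexpr("*", varP, fixed = TRUE)
    varP <- if (stopAt > 0) substr(varP, 1, stopAt) else varP
    okay <- switch(pc@kind,
      synonymous = identical(substr(varP, 1, nAA), refP),
      identity = identical(substr(varP, 1, nAA), refP),
      substitution = {
        i <- pc@startPos
        identical(substr(varP, 1, i - 1), substr(refP, 1, i - 1)) &&
          identical(hgvsConcord:::.aa3(substr(varP, i, i)), pc@altRes[1])
      },
      frameshift = {
        i <- pc@startPos
        identical(substr(varP, 1, i - 1), substr(refP, 1, i - 1)) &&
          (!length(pc@altRes) ||
             identical(hgvsConcord:::.aa3(substr(varP, i, i)),
                       pc@altRes[1])) &&
          (is.na(pc@fsNewStop) ||
             substr(varP, i + pc@fsNewStop - 1, i + pc@fsNewStop - 1) == "*")
      },
      deletion = {
        expected <- paste0(substr(refP, 1, pc@startPos - 1),
                           substr(refP, pc@endPos + 1, nAA))
        identical(varP, expected)
      },
      duplication = {
        unit <- substr(refP, pc@startPos, pc@endPos)
        expected <- paste0(substr(refP, 1, pc@endPos), unit,
                           substr(refP, pc@endPos + 1, nAA))
        identical(varP, expected)
      },
      insertion = {
        expected <- paste0(substr(refP, 1, pc@startPos),
                           paste(residueConvert(pc@altRes, "one"),
                                 collapse = ""),
                           substr(refP, pc@startPos + 1, nAA))
        identical(varP, expected)
      },
      delins = {
        expected <- paste0(substr(refP, 1, pc@startPos - 1),
                           paste(residueConvert(pc@altRes, "one"),
                                 collapse = ""),
                           substr(refP, pc@endPos + 1, nAA))
        identical(varP, expected)
      },
      extension = TRUE,       # exercised separately on the stop codon
      `unknown-start` = TRUE,
      FALSE)
    expect_true(okay, info = paste(kind, p, pc@kind))
    nOk <- nOk + okay
  }
  expect_equal(nOk, 400L)
})

test_that("effect terms co-vary with the protein change kind", {
  fx <- sharedFixture()
  g <- fx$genome
  txC <- fx$transcripts[["TXC00003.1"]]
  map <- c(substitution = "missense_variant", synonymous = "synonymous_variant",
           frameshift = "frameshift_variant", deletion = "inframe_deletion",
           duplication = "inframe_insertion", insertion = "inframe_insertion")
  set.seed(77)
  for (rep in 1:60) {
    p <- sample(200:8000, 1)
    w <- sample(c(1, 3), 1)
    refb <- substr(cdsSequence(txC, g), p, p + w - 1)
    a <- annotateVariant(
      list(contig = "ctgC",
           pos = cdnaToGenomic(txC, CdsCoord(p)) - 1L,
           ref = paste0(as.character(Biostrings::subseq(
             g[["ctgC"]], cdnaToGenomic(txC, CdsCoord(p)) - 1L,
             cdnaToGenomic(txC, CdsCoord(p)) - 1L)), refb),
           alt = as.character(Biostrings::subseq(
             g[["ctgC"]], cdnaToGenomic(txC, CdsCoord(p)) - 1L,
             cdnaToGenomic(txC, CdsCoord(p)) - 1L))),
      txC, g)
    if (is.null(a@protein)) next
    k <- a@protein@change@kind
    if (k %in% names(map))
      expect_true(map[[k]] %in% a@effects ||
                    (k == "substitution" && "stop_gained" %in% a@effects),
                  info = paste(p, w, k))
  }
})
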