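test_that("annotation-table readers handle the database dialects", {
  d <- withr::local_tempdir()
  ## clinvar-like with the hyphen deletion-allele convention
  cv <- data.frame(rsid = c("rs1", "rs2", ""),
                   alt = c("A", "-", "G"),
                   transcript = c("TXA00001.1", "TXA00001.1", "TXA00001.1"),
                   coding_hgvs = c("c.100A>G", "c.200delT", "c.1A>G"),
                   protein_hgvs = c("p.Lys34Glu", "", "p.Met1?"))
  f <- file.path(d, "cv.tsv")
  writeAnnotationTable(cv, f)
  rec <- readAnnotationTable(f, "clinvar-like")
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$rowStatus, c("ok", "ok", "malformed"))
  expect_equal(attr(rec, "nMalformed"), 1L)
  ## cosmic-like: one-letter protein syntax converted on read
  co <- data.frame(cosmid = c("COSM1", "COSM2"),
                   transcript = c("TXA00001.1", "TXA00001.1"),
                   coding_hgvs = c("c.1799T>A", "c.100G>T"),
                   protein_hgvs = c("p.V600E", "p.E34*"))
  f2 <- file.path(d, "co.tsv")
  writeAnnotationTable(co, f2)
  rec2 <- readAnnotationTable(f2, "cosmic-like")
  expect_equal(rec2$protein, c("p.Val600Glu", "p.Glu34Ter"))
  ## missing mandatory columns
  writeAnnotationTable(data.frame(x = 1), file.path(d, "bad.tsv"))
  expect_error(readAnnotationTable(file.path(d, "bad.tsv"), "tool-like"),
               "mandatory")
  ## empty table: empty record set and a summary of zeros
  writeAnnotationTable(cv[0, ], file.path(d, "empty.tsv"))
  rec3 <- readAnnotationTable(file.path(d, "empty.tsv"), "clinvar-like")
  expect_equal(nrow(rec3), 0L)
  s <- summarizeConcordance(hgvsConcord:::.emptyVerdicts())
  expect_equal(nrow(s), 0L)
})

test_that("joins use rsid+alt (hyphen for deletions) or the COSMID alone", {
  g <- sharedGenome()
  txA <- sharedTxA()
  gDel <- cdnaToGenomic(txA, CdsCoord(700L))
  b <- function(p, q = p) as.character(
    Biostrings::subseq(g[["ctgA"]], p, q))
  variants <- variantTable(
    c("ctgA", "ctgA", "ctgA"),
    c(cdnaToGenomic(txA, CdsCoord(500L)), gDel - 1L, gDel + 10L),
    c(b(cdnaToGenomic(txA, CdsCoord(500L))), b(gDel - 1L, gDel),
      b(gDel + 10L)),
    c("A", b(gDel - 1L), "T"),
    id = c("rs10", "rs11", NA))
  variants$alt[1] <- setdiff(c("A", "C", "G", "T"), variants$ref[1])[1]
  records <- data.frame(
    id = c("rs10", "rs11", "rs99", "rs10"),
    alt = c(variants$alt[1], "-", "G", variants$alt[1]),
    transcript = "TXA00001.1",
    coding = c("c.500N>N", "c.700del", "c.1A>G", "c.500N>N"),
    protein = "", rowStatus = "ok", source = "test")
  jn <- joinAnnotations(variants, records)
  expect_equal(nrow(jn$pairs), 2L)                 # rs10+alt, rs11 hyphen
  expect_equal(jn$unmatched$reason[jn$unmatched$recordRow == 3], "no-id-match")
  expect_equal(jn$unmatched$reason[jn$unmatched$recordRow == 4],
               "duplicate-key")
  ## cosmic-style id-only join ignores alt
  rec2 <- data.frame(id = "rs11", alt = NA_character_,
                     transcript = "TXA00001.1", coding = "c.700del",
                     protein = "", rowStatus = "ok", source = "t")
  jn2 <- joinAnnotations(variants, rec2)
  expect_equal(nrow(jn2$pairs), 1L)
})

test_that("truth-vs-truth evaluates 100% exact with full accounting", {
  fx <- sharedFixture()
  tr <- sharedTruth()
  nv <- normalizeVariants(tr$variants, fx$genome)
  res <- evaluateConcordance(tr$records, fx$transcripts, fx$genome,
                             variants = nv, mode = "generate")
  s <- res$summary
  expect_equal(sum(s$n), 2L * nrow(tr$records))
  expect_equal(sum(s$incorrect), 0L)
  expect_equal(sum(s$equivalent), 0L)
  expect_equal(sum(s$not_assessed), 0L)
  expect_equal(nrow(res$unmatched), 0L)
  ## denominator accounting per cell
  expect_true(all(s$exact + s$equivalent + s$incorrect + s$not_assessed ==
                    s$n))
  expect_true(all(abs(s$fracExact + s$fracEquivalent + s$fracIncorrect +
                        s$fracNotAssessed - 1) < 1e-12 | s$n == 0))
})

test_that("version-mismatched transcripts are counted not_assessed and excluded", {
  fx <- sharedFixture()
  tr <- sharedTruth()
  rec <- tr$records[1:10, ]
  rec$transcript[1:3] <- sub("\\.1$", ".2", rec$transcript[1:3])
  nv <- normalizeVariants(tr$variants, fx$genome)
  res <- evaluateConcordance(rec, fx$transcripts, fx$genome,
                             variants = nv, mode = "generate")
  s <- res$summary
  expect_equal(sum(s$not_assessed), 6L)   # 3 records x 2 levels
  na <- res$verdicts[res$verdicts$status == "not_assessed", ]
  expect_true(all(grepl("transcript-version-mismatch", na$reasons)))
  expect_true(all(s$nAssessed == s$n - s$not_assessed))
})

test_that("reports round-trip and reason tags account for every non-exact verdict", {
  fx <- sharedFixture()
  tr <- sharedTruth()
  rates <- list("star-for-Ter" = 1, "no-right-shift" = 1)
  co <- corruptAnnotations(tr$records, fx, rates = rates, seed = 3)
  res <- evaluateConcordance(co$records, fx$transcripts, fx$genome,
                             reference = tr$records, mode = "compare")
  d <- withr::local_tempdir()
  writeConcordanceReport(res, file.path(d, "rep"))
  back <- readConcordanceReport(file.path(d, "rep"))
  expect_equal(nrow(back$verdicts), nrow(res$verdicts))
  expect_equal(as.integer(back$summary$exact), res$summary$exact)
  ## every equivalent/incorrect verdict carries at least one reason tag
  ne <- res$verdicts[res$verdicts$status %in% c("equivalent", "incorrect"), ]
  expect_true(all(nzchar(ne$reasons)))
  ## zero-record run still writes a valid report
  empty <- evaluateConcordance(tr$records[0, ], fx$transcripts, fx$genome,
                               reference = tr$records, mode = "compare")
  writeConcordanceReport(empty, file.path(d, "empty"))
  expect_silent(readConcordanceReport(file.path(d, "empty")))
})

test_that("identical inputs and seed produce byte-identical reports", {
  fx <- sharedFixture()
  tr <- sharedTruth()
  d <- withr::local_tempdir()
  for (run in 1:2) {
    co <- corruptAnnotations(tr$records, fx,
                             rates = list("one-letter-protein" = 0.5),
                             seed = 17)
    res <- evaluateConcordance(co$records, fx$transcripts, fx$genome,
                               reference = tr$records, mode = "compare")
    writeConcordanceReport(res, file.path(d, paste0("run", run)))
  }
  expect_identical(readLines(file.path(d, "run1.json")),
                   readLines(file.path(d, "run2.json")))
  expect_identical(readLines(file.path(d, "run1_verdicts.tsv")),
                   readLines(file.path(d, "run2_verdicts.tsv")))
})
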