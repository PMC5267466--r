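test_that("left alignment is parsimonious, left-most and idempotent", {
  ## CCCC homopolymer: insertion reported mid-run normalizes to the run's
  ## left flank
  s <- "ACGTACGTGACCCCTTGACGTACGTACGTACGTACGTACG"
  g <- Biostrings::DNAStringSet(c(toy = s))
  v <- variantTable("toy", 12, "C", "CC")   # run occupies 11..14
  la <- leftAlign(v, g)
  expect_equal(la$pos, 10L)
  expect_equal(la$ref, "A")
  expect_equal(la$alt, "AC")
  expect_identical(leftAlign(la, g), la)
  ## SNVs are unchanged
  v <- variantTable("toy", 5, "A", "G")
  expect_identical(leftAlign(v, g), v)
  ## reference mismatch is signalled
  expect_error(leftAlign(variantTable("toy", 5, "T", "G"), g),
               class = "referenceMismatch")
})

test_that("left alignment maps all sequence-identical representations to one record", {
  ## brute-force oracle on a 40-bp fixture: enumerate anchored edits, group
  ## by the edited sequence, and require one normalized form per group
  set.seed(9)
  s <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE,
                    prob = c(.4, .3, .2, .1)), collapse = "")
  g <- Biostrings::DNAStringSet(c(toy = s))
  reprs <- list()
  for (pos in 2:36) {
    anchor <- substr(s, pos, pos)
    for (k in 1:3) {        # deletions of k bases after pos
      if (pos + k > 40) next
      ref <- substr(s, pos, pos + k)
      reprs[[length(reprs) + 1L]] <- list(pos = pos, ref = ref,
                                          alt = anchor)
    }
    for (ins in c("A", "C", "G", "T", "AC", "CA", "CC", "GT", "TG",
                  "AAC", "CCA")) {
      reprs[[length(reprs) + 1L]] <-
        list(pos = pos, ref = anchor, alt = paste0(anchor, ins))
    }
  }
  edited <- vapply(reprs, function(r)
    applyVcfEdit(s, r$pos, r$ref, r$alt), character(1))
  norm <- vapply(reprs, function(r) {
    la <- leftAlign(variantTable("toy", r$pos, r$ref, r$alt), g)
    paste(la$pos, la$ref, la$alt)
  }, character(1))
  expect_gt(length(reprs), 400)
  for (grp in split(norm, edited))
    expect_length(unique(grp), 1)
})

test_that("dedupe is keyed on alleles and merges provenance ids", {
  g <- sharedGenome()
  txA <- sharedTxA()
  ## the same insertion encoded at two in-repeat positions (the CCCC run
  ## at coding 402..405): one record after normalization
  gRun <- cdnaToGenomic(txA, CdsCoord(402L))
  v <- variantTable(c("ctgA", "ctgA"), c(gRun, gRun + 2L), c("C", "C"),
                    c("CC", "CC"), id = c("rs1", "rs2"))
  dd <- dedupeVariants(leftAlign(v, g))
  expect_equal(nrow(dd), 1L)
  expect_equal(dd$id, "rs1;rs2")
  ## disjoint variants are untouched; n copies collapse to 1
  v2 <- variantTable("ctgA", c(600, 700, 700, 700), "AC", "A",
                     id = c("a", "b", NA, "b"))
  v2$ref <- substr(rep(as.character(g[["ctgA"]]), 4), v2$pos, v2$pos + 1)
  v2$alt <- substr(v2$ref, 1, 1)
  dd2 <- dedupeVariants(v2)
  expect_equal(nrow(dd2), 2L)
  expect_equal(dd2$id[2], "b")
})

test_that("phased adjacent SNVs merge into block substitutions", {
  g <- sharedGenome()
  txA <- sharedTxA()
  g1798 <- cdnaToGenomic(txA, CdsCoord(1798L))
  b <- function(p) as.character(Biostrings::subseq(g[["ctgA"]], p, p))
  phased <- variantTable("ctgA", c(g1798, g1798 + 1L),
                         c(b(g1798), b(g1798 + 1L)), c("A", "A"),
                         id = c("v1", "v2"), phaseGroup = "PS1")
  m <- mergePhasedMnv(phased)
  expect_equal(nrow(m), 1L)
  expect_equal(m$ref, "GT")
  expect_equal(m$alt, "AA")
  ## unphased neighbours stay separate
  unphased <- phased
  unphased$phaseGroup <- NA_character_
  expect_equal(nrow(mergePhasedMnv(unphased)), 2L)
  ## phased but non-adjacent SNVs stay separate
  apart <- variantTable("ctgA", c(g1798, g1798 + 5L),
                        c(b(g1798), b(g1798 + 5L)), c("A", "A"),
                        phaseGroup = "PS1")
  expect_equal(nrow(mergePhasedMnv(apart)), 2L)
  ## merging never changes the edited-sequence outcome
  s <- as.character(g[["ctgA"]])
  e1 <- applyVcfEdit(applyVcfEdit(s, g1798, b(g1798), "A"),
                     g1798 + 1L, b(g1798 + 1L), "A")
  e2 <- applyVcfEdit(s, m$pos, m$ref, m$alt)
  expect_identical(e1, e2)
})

test_that("3'-shifting honors repeats and the intron-exon boundary exception", {
  g <- sharedGenome(); txA <- sharedTxA()
  fmt <- function(ch) hgvsConcord:::.formatCodingChange(ch)
  ## donor-side tandem: shifting toward the boundary is required
  sh <- shift3Coding(parseCoding("c.1895+1_1895+4delGTGA")@change, txA, g)
  expect_equal(fmt(sh), "1895+5_1895+8delGTGA")
  ## acceptor-side run: shifting across the boundary is forbidden
  sh <- shift3Coding(parseCoding("c.1200-1delG")@change, txA, g)
  expect_equal(fmt(sh), "1200-1delG")
  ## the same G run approached from the exon side stays exonic
  sh <- shift3Coding(parseCoding("c.1200delG")@change, txA, g)
  expect_equal(fmt(sh), "1201delG")
  ## insertion in the CCCC run becomes a duplication of the run's 3' base
  sh <- shift3Coding(parseCoding("c.404_405insC")@change, txA, g)
  expect_equal(fmt(sh), "405dup")
  ## 9-mer insertion equal to the 5'-adjacent bases becomes a 9-mer dup
  sh <- shift3Coding(parseCoding("c.2339_2340insGGGCTCCCC")@change, txA, g)
  expect_equal(fmt(sh), "2331_2339dup")
  ## idempotence
  expect_equal(fmt(shift3Coding(sh, txA, g)), "2331_2339dup")
})

test_that("delins reduction strips shared flanks and reclassifies", {
  fmt <- function(ch) hgvsConcord:::.formatCodingChange(ch)
  expect_equal(fmt(reduceDelins(parseCoding("c.1960delCinsCG")@change)),
               "1960_1961insG")
  expect_equal(fmt(reduceDelins(parseCoding("c.3141_3142delGAinsTT")@change)),
               "3141_3142delinsTT")
  expect_equal(fmt(reduceDelins(parseCoding("c.100delAinsG")@change)),
               "100A>G")
  ## reduction then dup detection: the VR redundant-delins dialect
  g <- sharedGenome(); txA <- sharedTxA()
  red <- reduceDelins(parseCoding("c.404delCinsCC")@change)
  expect_equal(fmt(shift3Coding(red, txA, g)), "405dup")
})

test_that("shift3 maps all sequence-identical coding representations to one form", {
  ## exhaustive oracle on a 48-bp single-exon transcript
  set.seed(21)
  s <- paste(sample(c("A", "C", "G", "T"), 48, replace = TRUE,
                    prob = c(.35, .3, .2, .15)), collapse = "")
  toy <- toyTx(s)
  keys <- character(); edits <- character()
  for (p in 2:46) {
    for (k in 1:2) {                       # deletions
      if (p + k - 1L > 47) next
      ch <- new("CodingChange", kind = "deletion", start = CdsCoord(p),
                end = CdsCoord(p + k - 1L),
                refBases = substr(s, p, p + k - 1L))
      keys <- c(keys, hgvsConcord:::.formatCodingChange(
        shift3Coding(ch, toy$tx, toy$genome)))
      edits <- c(edits, paste0("D", applyCodingChange(ch, toy$tx,
                                                      toy$genome)))
    }
    for (ins in c("A", "C", "G", "T", "AC", "CA", "GT")) {  # insertions
      ch <- new("CodingChange", kind = "insertion", start = CdsCoord(p),
                end = CdsCoord(p + 1L), altBases = ins)
      keys <- c(keys, hgvsConcord:::.formatCodingChange(
        shift3Coding(ch, toy$tx, toy$genome)))
      edits <- c(edits, paste0("I", applyCodingChange(ch, toy$tx,
                                                      toy$genome)))
    }
  }
  for (grp in split(keys, edits))
    expect_length(unique(grp), 1)
})

test_that("left-aligned and 3'-shifted descriptions edit to the same sequence", {
  ## left/right duality on a single-exon toy transcript: the VCF-style
  ## left-most form and the HGVS right-most form of one allele produce
  ## identical edited sequences
  set.seed(4)
  s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  toy <- toyTx(s)
  for (p in c(5L, 17L, 30L, 44L)) {
    ch <- new("CodingChange", kind = "deletion", start = CdsCoord(p),
              end = CdsCoord(p), refBases = substr(s, p, p))
    right <- shift3Coding(ch, toy$tx, toy$genome)
    v <- leftAlign(variantTable("toy", p - 1L,
                                substr(s, p - 1L, p), substr(s, p - 1L, p - 1L)),
                   toy$genome)
    viaVcf <- applyVcfEdit(s, v$pos, v$ref, v$alt)
    viaHgvs <- applyCodingChange(right, toy$tx, toy$genome)
    expect_identical(viaVcf, viaHgvs)
  }
})

test_that("normalization pipeline composes and preserves record identity", {
  g <- sharedGenome()
  gRun <- cdnaToGenomic(sharedTxA(), CdsCoord(402L))
  v <- variantTable(c("ctgA", "ctgA"), c(gRun, gRun + 2L), c("C", "C"),
                    c("CC", "CC"), id = c("a", "b"))
  nv <- normalizeVariants(v, g)
  expect_equal(nrow(nv), 1L)
  expect_equal(variantType(nv, g), "duplication")
})
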