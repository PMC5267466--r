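## Shared fixture, built once per test run.

.fixtureCache <- new.env(parent = emptyenv())

sharedFixture <- function(seed = 1L) {
  key <- paste0("fx", seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- makeFixture(simulationConfig(seed = seed))
  .fixtureCache[[key]]
}

sharedTruth <- function(seed = 1L) {
  key <- paste0("tr", seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- makeTruth(simulationConfig(seed = seed),
                                      sharedFixture(seed))
  .fixtureCache[[key]]
}

sharedTxA <- function() sharedFixture()$transcripts[["TXA00001.1"]]
sharedTxB <- function() sharedFixture()$transcripts[["TXB00002.1"]]
sharedGenome <- function() sharedFixture()$genome

## Small standalone transcript for enumeration oracles: one contig, one or
## two exons, fully exonic CDS with no UTRs.
toyTx <- function(seqstr, strand = "+", exons = NULL) {
  n <- nchar(seqstr)
  if (is.null(exons)) exons <- cbind(1L, n)
  width <- sum(exons[, 2] - exons[, 1] + 1L)
  list(genome = Biostrings::DNAStringSet(c(toy = seqstr)),
       tx = TranscriptModel("TOY00001", 1L, "TOY", "toy", strand, exons,
                            cdsStart = 1L, cdsEnd = width))
}

## Apply a VCF-style record to a contig sequence (string edit oracle).
applyVcfEdit <- function(seqstr, pos, ref, alt) {
  stopifnot(substr(seqstr, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(seqstr, 1L, pos - 1L), alt,
         substr(seqstr, pos + nchar(ref), nchar(seqstr)))
}

## Random transcript models for coordinate property tests.
randomTx <- function(seed, strand = "+") {
  set.seed(seed)
  nE <- sample(2:4, 1)
  widths <- sample(30:80, nE, replace = TRUE)
  gaps <- sample(20:60, nE - 1, replace = TRUE)
  starts <- integer(nE); ends <- integer(nE)
  cur <- sample(5:20, 1)
  for (k in seq_len(nE)) {
    starts[k] <- cur
    ends[k] <- cur + widths[k] - 1L
    cur <- ends[k] + (if (k < nE) gaps[k] else 0L) + 1L
  }
  txLen <- sum(widths)
  cdsStart <- sample(3:10, 1)
  cdsLen <- ((txLen - cdsStart - 5L) %/% 3L) * 3L
  contigLen <- ends[nE] + 10L
  seqstr <- paste(sample(c("A", "C", "G", "T"), contigLen, replace = TRUE),
                  collapse = "")
  list(genome = Biostrings::DNAStringSet(c(rnd = seqstr)),
       tx = TranscriptModel("RND00001", 1L, "RND", "rnd", strand,
                            cbind(starts, ends), cdsStart = cdsStart,
                            cdsEnd = cdsStart + cdsLen - 1L))
}
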