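test_that("coding dialects parse to the right change with flags recorded", {
  cases <- list(
    list("NM_000277.1:c.1200-1delG", "deletion", character()),
    list("c.3141_3142GA>TT", "delins", "substitution-style-indel"),
    list("c.2262_2263ins14", "insertion", "length-only-insertion"),
    list("c.1895 + 5_1895 + 8delGTGA", "deletion", "whitespace"),
    list("c.2199-1301GA > A", "delins", c("whitespace", "missing-del")),
    list("c.1621A=", "identity", character()),
    list("c.2331_2339dupGGGCTCCCC", "duplication", "restated-bases"))
  for (cs in cases) {
    e <- parseCoding(cs[[1]])
    expect_equal(e@change@kind, cs[[2]], info = cs[[1]])
    expect_setequal(e@dialectFlags, cs[[3]])
  }
  e <- parseCoding("NM_000277.1:c.1200-1delG")
  expect_equal(e@accession, "NM_000277")
  expect_equal(e@version, 1L)
  expect_equal(e@change@start@anchor, 1200L)
  expect_equal(e@change@start@offset, -1L)
  e <- parseCoding("c.2262_2263ins14")
  expect_equal(e@change@insLength, 14L)
})

test_that("protein dialects parse and normalize residues", {
  e <- parseProtein("p.Arg227LysfsTer31")
  expect_equal(e@change@kind, "frameshift")
  expect_equal(e@change@fsNewStop, 31L)
  expect_false(e@change@fsLowerBound)

  e <- parseProtein("p.P1176fs*>46")
  expect_equal(e@change@kind, "frameshift")
  expect_true(e@change@fsLowerBound)
  expect_equal(e@change@startRes, "Pro")
  expect_true("one-letter-aa" %in% e@dialectFlags)

  e <- parseProtein("p.*1133L")
  expect_equal(e@change@kind, "extension")
  expect_equal(e@change@altRes, "Leu")
  expect_true(is.na(e@change@extNewStop))

  e <- parseProtein("p.Gln100*")
  expect_equal(e@change@kind, "substitution")
  expect_equal(e@change@altRes, "Ter")
  expect_true("star-for-Ter" %in% e@dialectFlags)

  for (txt in c("p.=", "p.(=)"))
    expect_equal(parseProtein(txt)@change@kind, "identity")
  for (txt in c("p.Arg317Arg", "p.Arg317="))
    expect_equal(parseProtein(txt)@change@kind, "synonymous")
})

test_that("gibberish is rejected, not guessed at", {
  for (bad in c("c.foo", "c.12xx>G", "p.12", "p.Arg", "c.", "nonsense",
                "c.10_11insXY", "p.Glu238ins"))
    expect_error(parseHgvs(bad), class = "hgvsParseError")
})

test_that("residue conversion is bijective with Ter handling", {
  for (one in hgvsConcord:::.aminoAcids1)
    expect_equal(residueConvert(residueConvert(one), "one"), one)
  for (three in hgvsConcord:::.aminoAcids3)
    expect_equal(residueConvert(residueConvert(three, "one")), three)
  expect_equal(residueConvert("*"), "Ter")
  expect_equal(residueConvert("X"), "Ter")
  expect_equal(residueConvert("Ter", "one"), "*")
  expect_error(residueConvert("B"))
})

test_that("preferred formatting matches the house style", {
  expect_equal(formatPreferred(parseCoding("c.68-5_68-3delCTCinsTT")),
               "c.68-5_68-3delinsTT")
  expect_equal(formatPreferred(parseCoding("c.428dupA")), "c.428dup")
  expect_equal(formatPreferred(parseProtein("p.Arg317Arg")), "p.Arg317=")
  expect_equal(formatPreferred(parseProtein("p.*1143*")), "p.Ter1143=")
  expect_equal(formatPreferred(parseProtein("p.V600E")), "p.Val600Glu")
  expect_equal(formatPreferred(parseProtein("p.Gln256>ArgGlu")),
               "p.Gln256delinsArgGlu")
  ## deletions keep their bases when stated
  expect_equal(formatPreferred(parseCoding("c.1895+5_1895+8delGTGA")),
               "c.1895+5_1895+8delGTGA")
})

.randomCodingChange <- function(seed) {
  set.seed(seed)
  kind <- sample(c("substitution", "deletion", "duplication", "insertion",
                   "delins", "identity"), 1)
  a <- sample(c(-20:-1, 1:500), 1)
  w <- sample(0:5, 1)
  start <- CdsCoord(a)
  end <- hgvsConcord:::.coordAdd(start, w)
  bases <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")
  switch(kind,
    substitution = new("CodingChange", kind = kind, start = start,
                       end = start, refBases = "A", altBases = "G"),
    identity = new("CodingChange", kind = kind, start = start, end = start,
                   refBases = sample(c(NA_character_, "C"), 1)),
    deletion = new("CodingChange", kind = kind, start = start, end = end,
                   refBases = bases(w + 1L)),
    duplication = new("CodingChange", kind = kind, start = start,
                      end = end),
    insertion = new("CodingChange", kind = kind, start = start,
                    end = hgvsConcord:::.coordAdd(start, 1L),
                    altBases = bases(sample(1:6, 1))),
    delins = new("CodingChange", kind = kind, start = start, end = end,
                 altBases = bases(sample(2:5, 1))))
}

test_that("parse . formatPreferred is the identity on change structure", {
  for (seed in 1:60) {
    ch <- .randomCodingChange(seed)
    txt <- formatPreferred(new("HgvsExpression", molecule = "c",
                               change = ch, raw = ""))
    e <- parseCoding(txt)
    expect_equal(e@change@kind, ch@kind, info = txt)
    expect_true(hgvsConcord:::.coordEqual(e@change@start, ch@start),
                info = txt)
    expect_true(hgvsConcord:::.coordEqual(e@change@end, ch@end), info = txt)
    expect_identical(e@change@altBases, ch@altBases, info = txt)
    ## formatting is idempotent
    expect_identical(formatPreferred(e), txt)
    expect_length(setdiff(e@dialectFlags, "restated-bases"), 0)
  }
})
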