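# hgvsConcord

Clinical variant interpretation depends on matching a variant called on
genomic coordinates (VCF) against knowledge stored as transcript- or
protein-level HGVS descriptions (`NM_004333.4:c.1799T>A`, `p.Val600Glu`).
The two conventions disagree in exactly the situations that matter most:
inside nucleotide repeats VCF left-aligns while HGVS 3'-shifts, duplications
can be written as insertions, delins as substitutions, frameshifts in long
or short form, and transcript accessions and versions drift between
resources. hgvsConcord is an R package for quantifying that discordance: it
generates canonical HGVS from genomic variants, canonicalizes the dialects
found in real databases, classifies pairs of descriptions as **exact /
equivalent / incorrect / not assessed**, and summarizes concordance by
variant type — all on fully synthetic fixtures with known ground truth and
injectable, labelled error modes.

It is aimed at bioinformaticians who maintain annotation pipelines or curate
variant knowledge bases and want a tested, self-contained harness for
validating HGVS handling.

## What it implements

* **Coordinate model** (`TranscriptModel`, `genomicToCdna`,
  `cdnaToGenomic`, `cdsSequence`): exon/CDS structure on a fixture genome,
  strand-aware mapping between genomic, transcript and CDS coordinates with
  HGVS intron offsets (`c.1895+5`, `c.1200-1`, `c.*4`), and
  transcript-versus-genome reference overrides (positions where the curated
  transcript carries a different base than the assembly, so a matching
  "variant" is an identity, `c.1621G=`).
* **HGVS parser/formatter** (`parseCoding`, `parseProtein`,
  `formatPreferred`): the preferred syntax plus the observed dialects —
  one-letter residues, `*`/`X` for `Ter`, `c.3141_3142GA>TT`,
  `c.2262_2263ins14`, missing `del` designators, `fs*>N` — every tolerance
  recorded as a dialect flag.
* **Normalization** (`leftAlign`, `mergePhasedMnv`, `dedupeVariants`,
  `shift3Coding`, `reduceDelins`): vt-style left alignment
  (trim shared flanks, extend left; parsimonious and idempotent), phased
  adjacent SNVs merged into block substitutions (MNVs), HGVS 3'-shifting
  with the intron–exon boundary exception, duplication detection
  (`c.404_405insC` → `c.405dup`) and delins reduction
  (`c.1960delCinsCG` → `c.1961dup`).
* **Annotation** (`annotateVariant`, `translateConsequence`,
  `classifyEffect`): canonical coding HGVS, protein consequence by direct
  translation of the edited CDS (frameshift long forms `p.ProNAlafsTerM`,
  extensions `p.TerNLeuextTerM`, residue-level duplications, the
  immediate-stop rule `p.Ile55Ter`), and Sequence Ontology effect terms.
* **Equivalence classifier** (`compareExpressions`, `canonicalKey`): the
  transcript gate (accession *and* version must match, else
  `not_assessed`), as-is matches are `exact`, rule-tagged closure for
  `equivalent`, everything else `incorrect` with diagnostic reasons
  (`shift-difference`, `dup-vs-ins`, `fs-form`, ...).
* **Dataset pipeline** (`readAnnotationTable`, `joinAnnotations`,
  `evaluateConcordance`, `writeConcordanceReport`): ClinVar-like
  (rsid + alt, hyphen deletion alleles) and COSMIC-like (COSMID, one-letter
  protein) table readers, per-variant-type concordance summaries with full
  denominator accounting.
* **Synthetic data** (`simulationConfig`, `makeFixture`, `makeTruth`,
  `corruptAnnotations`): deterministic fixture genomes with planted repeat
  contexts (homopolymers, tandem units, junction-spanning runs), truth sets
  with canonical annotations, and eleven labelled corruption modes
  (failure to right-shift, 11-base over-shift, dup-as-ins, redundant
  delins, substitution-style indels, fs short forms, one-letter residues,
  star-for-Ter, missing `del`, version bumps, protein claims on intronic
  variants).

A thin command-line wrapper with `annotate` / `compare` / `simulate` /
`report` subcommands is installed at `inst/scripts/hgvs-concordance.R`.

## Worked example

```r
library(hgvsConcord)

fx  <- makeFixture(simulationConfig(seed = 1))
txA <- fx$transcripts[["TXA00001.1"]]
g   <- fx$genome

## a missense SNV at codon 600 of the plus-strand fixture transcript
p <- cdnaToGenomic(txA, CdsCoord(1799))
annotateVariant(list(contig = "ctgA", pos = p, ref = "T", alt = "A"), txA, g)
#> AnnotationResult [annotated] TXA00001.1
#>   coding:  TXA00001.1:c.1799T>A
#>   protein: TXA00001.1:p.Val600Glu
#>   effects: missense_variant

## the same two bases as a phased dinucleotide block change the call
annotateVariant(list(contig = "ctgA", pos = p - 1, ref = "GT", alt = "AA"),
                txA, g)
#> AnnotationResult [annotated] TXA00001.1
#>   coding:  TXA00001.1:c.1798_1799delinsAA
#>   protein: TXA00001.1:p.Val600Lys
#>   effects: missense_variant

## dialect-tolerant comparison
compareExpressions("p.Gln100*", "p.Gln100Ter")
#> MatchVerdict: equivalent (star-for-Ter)
compareExpressions("NM_000277.1:c.1200delG", "NM_000277.1:c.1200-1delG")
#> MatchVerdict: incorrect (shift-difference)
compareExpressions("NM_005228.3:c.1A>G", "NM_005228.4:c.1A>G")
#> MatchVerdict: not_assessed (transcript-version-mismatch)
```

The first verdict says the two nonsense spellings describe the same variant
(`equivalent`, with the tolerance that was needed); the second is a genuine
error — the deletion was right-shifted across an intron–exon boundary where
the 3' rule does not apply; the third cannot be assessed because the
transcript versions differ.

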