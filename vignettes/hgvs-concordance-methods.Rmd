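---
title: "Methods: measuring concordance of HGVS variant nomenclature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring concordance of HGVS variant nomenclature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A genomic variant has one natural description in VCF space (contig,
position, reference and alternative alleles) and several in HGVS space
(coding `c.` and protein `p.` descriptions against a transcript accession).
Inside sequence repeats the two standards deliberately disagree: VCF places
ambiguous indels at their left-most genomic position with a shared anchor
base, while HGVS requires the most 3' (right-most) position relative to the
transcript — *except* across intron–exon boundaries, where shifting would
change the biological interpretation of a splice-site variant. On top of
that positional ambiguity, databases and tools emit a zoo of dialects:
one-letter amino acids, `*` or `X` for the stop codon, duplications written
as insertions, delins written as substitutions, frameshifts in long and
short form.

hgvsConcord implements the full round trip — generate canonical HGVS from
genomic variants, canonicalize foreign dialects, classify pairs of
descriptions, and summarize discordance by variant type — so that the
behaviour of an annotation pipeline can be validated against synthetic data
whose ground truth is known by construction.

# Coordinate model

Internally all coordinates live in a single "locus index" axis: position 1
is the 5' end of the transcript locus, increasing in transcript direction
and covering introns. This makes strand handling and intron offsets plain
integer arithmetic; the 0-based/1-based and inclusive/half-open conventions
of VCF and HGVS exist only at the surfaces.

HGVS intron offsets anchor to the *nearest* exon boundary. The standard
does not state a tie rule for the midpoint of an intron; we split each
intron at its midpoint and assign the middle base of odd-length introns to
the upstream (donor) exon. This choice is arbitrary but deterministic, and
it only affects which of two equally valid anchors is printed — never which
genomic base is meant.

Transcript-versus-genome reference overrides are stored per transcript as
(genomic position, transcript base) pairs. A variant whose alternative
allele equals the transcript base is reported as an identity
(`c.1621G=`) with `refDifference = TRUE`, because at transcript level there
is no change to describe.

# Normalization

**Left alignment** follows the vt algorithm: repeatedly trim a shared
terminal base and, when an allele empties, extend both alleles one
reference base to the left; finally trim shared leading bases down to a
single anchor. The result is parsimonious, left-most, and a fixed point of
the procedure.

**3'-shifting** operates in locus-index space and is region-bounded: a
fully intronic change may not move into an exon and a fully exonic change
may not move into an intron, in either direction, while shifting that
merely approaches the boundary is required. Deletions shift while the base
following the deleted block equals its first base; insertions rotate their
inserted string while its first base equals the next reference base. After
shifting, an insertion whose bases equal the immediately 5'-adjacent
accession sequence is emitted as a duplication. For exonic insertions the
adjacency check runs on the spliced transcript (the copied bases may lie in
the previous exon); for intronic insertions it is intron-local.
Junction-spanning changes are left as written.

**Delins reduction** strips bases shared between the deleted and inserted
strings (greedy prefix, then suffix — which also minimizes the deleted-base
count, our tie-break for equally right-most representations) and then
reclassifies the remainder: empty deletion side → insertion (which may
become a duplication), empty insertion side → deletion, 1:1 → substitution.

**Phased MNV merging** collapses adjacent single-nucleotide records that
share a phase-group label into one block substitution. Unphased neighbours
stay separate — deliberately, because merging unphased records would invent
haplotypes; this is exactly the situation in which pipelines mis-annotate a
dinucleotide variant as two independent substitutions with different
protein consequences.

# Protein consequence

The consequence caller translates the edited CDS directly and compares it
with the reference protein; there is no codon-table special-casing to get
out of sync with the sequence. Greedy prefix alignment (which realizes
residue-level 3'-shifting), then suffix trimming for in-frame events,
yields the changed interval. Rules worth noting:

* If the first changed residue is itself a stop, the call is a nonsense
  substitution (`p.Ile55Ter`) — not a frameshift — even when the underlying
  nucleotide event is a deletion.
* Frameshifts use the long form (`p.Pro234LeufsTer17`) whenever the new
  stop is reachable in the available sequence, the short form otherwise.
* Stop-loss becomes an extension with the distance to the next in-frame
  stop in the 3' UTR (`p.Ter801TrpextTer22`), or an unknown marker when no
  stop exists in the modeled sequence.
* An in-frame insertion that copies the adjacent residues is a
  residue-level duplication (`p.Gly778_Pro780dup`), found by the same
  shift-then-compare logic at residue granularity.
* Start-codon-disrupting variants get minimal support only: `p.Met1?`.

Sequence Ontology terms are derived from the coordinate context (intron
offsets within ±2 are splice donor/acceptor, ±3..8 splice region; UTR
anchors map to the UTR terms) and, for CDS variants, co-vary exactly with
the protein change kind. Intronic and UTR variants never carry a protein
expression.

# The comparator

Comparison is gated on the transcript: if both sides name an accession and
either the accession or the version differs, the verdict is `not_assessed`
and the pair is excluded from concordance denominators (but reported). An
as-is match (ignoring whitespace and the accession prefix) is `exact`.

For `equivalent`, the default mode applies the *string-level* closure only:
dialect normalization (residue codes, `Ter` spellings, parentheses),
delins reduction, the single-base insertion/duplication adjacency rule, the
length-only-insertion rule (`ins14` matches a base-explicit insertion of
length 14, but can never be `exact`), `p.=` matching any synonymous
description, frameshift short forms matching long forms (`fs*>N` matches a
long form only when N agrees), and a frameshift whose stop distance is 1
matching the nonsense substitution. Crucially, the default mode does *not*
re-shift positions or merge multi-base insertions with duplications: a
description at the wrong position is a wrong description, which is also the
conservative choice when no reference sequence is at hand to verify
duplicated bases. With a transcript supplied and `verify = TRUE`, the
comparator additionally canonicalizes both sides against the sequence
(3'-shifting, duplication detection, residue validation), which is the mode
used to show that a discrepant representation denotes the same allele.

`canonicalKey()` exposes the normal form as a string; equal keys imply
equivalence. The optional-field semantics above (short vs long frameshift
forms, length-only insertions, bare `p.=`) cannot be encoded in one string
per expression, so the comparator layers rule-tagged pairwise checks on top
of key equality; every non-exact verdict carries its rule tags, making the
implemented closure auditable record by record.

# Synthetic data

`makeFixture()` builds a three-contig genome with three transcripts:

* **TXA00001.1** (plus strand, 801 codons, three exons) carries the
  hard-coded edge-case loci: a CCCC homopolymer at coding 402–405, an
  AAAAAA run at 423–428, an AGC×3 tandem at 1948–1956, a GTGAGTGAC intron
  start after coding 1895, a G run spanning the intron/exon boundary at
  coding 1200, a Gly-Ser-Pro 9-mer duplication context at 2331–2340
  (residues 778–780), an Arg run at residues 309–311, a reference override
  at c.1621 (genome A, transcript G), Val at codon 600, and a 3' UTR whose
  first in-frame stop sits 22 codons past the CDS stop.
* **TXB00002.1** (minus strand, 301 codons) exercises strand arithmetic and
  carries a planted exonic G homopolymer.
* **TXC00003.1** (plus strand, 3001 codons) provides bulk coding space so
  that large truth sets can be placed without overlap.

Background sequence is drawn from sense codons under the configured seed;
the planted loci are identical under every seed, so the worked examples are
reproducible while everything else varies. Planted repeats are recorded in
a manifest.

`makeTruth()` samples records per class (the default totals 126 across
SNVs, nonsense SNVs, deletions, duplications, insertions, delins, phased
MNVs, intronic and UTR variants, plus the override identity record).
Deletions are placed inside repeat runs so that 3'-shifting is always
exercised (and the failure-to-right-shift corruption always applicable);
insertions are re-drawn until they are not duplications; records are kept
genomically disjoint so de-duplication and phased merging stay unambiguous.
Every truth annotation is produced by `annotateVariant()` itself and
spot-checked in the test suite against an independent sequence-application
oracle.

`corruptAnnotations()` hits each record independently with each error mode
at its configured rate, using per-record sub-seeds so that record sets are
reproducible. The modes mimic failure patterns observed in real databases
and tools; by construction the dialect-class modes (fs short form,
one-letter residues, star-for-Ter, redundant delins, substitution-style
indels, missing `del`) evaluate as `equivalent`, the error-class modes
(failure to right-shift, 11-base over-shift, dup-as-ins, fabricated protein
syntax on intronic variants) as `incorrect`, and version bumps as
`not_assessed`. The label table records exactly which modes fired on which
records, so injected rates can be compared with the verdict-tag frequencies
the pipeline reports.

What the generator does *not* emulate: real genome scale and repeat
density, multi-transcript loci sharing exons, population allele frequencies,
RNA-level splice-product annotations (exon-skipping consequences of an SNV
are out of scope and would be marked not-comparable, not incorrect), and
the full column schemas of real database exports. Passing tests therefore
demonstrate correctness of the normalization, annotation and comparison
logic on controlled sequence contexts, not performance on a production
release of a variant database.

# Numerical and design choices

* Default comparison is sequence-free (conservative); sequence-aware
  verification is opt-in per call.
* Duplication is preferred over insertion whenever the duplicated-bases
  check against the reference succeeds; without sequence, multi-base
  insertions and duplications are never merged.
* Preferred output style: deletions retain their bases when known,
  duplications and delins never restate them; three-letter residues; `Ter`;
  no parentheses around protein changes (none of the compared sources use
  them); intronic `c.` positions are accepted and emitted.
* De-duplication keys ignore record ids; colliding ids are concatenated as
  provenance.
* When a source supplies several annotations for one variant and
  transcript, the first is evaluated; reader order is preserved.
* Each (variant, transcript) pair is evaluated independently.
* Fixture accessions use an obviously synthetic namespace (TXA00001.1,
  ...) so they cannot be mistaken for real RefSeq/Ensembl records.

# Problem sizes

The test suite runs the enumeration oracles on 40–50 bp fixtures
(roughly a thousand representations each for left alignment and
3'-shifting), checks translation consistency on 1000 random coding changes
against direct translation, and recovers corruption rates on a 1000-record
truth set with rates 0.2 (failure to right-shift, deletions), 0.3
(dup-as-ins, duplications) and 0.5 (star-for-Ter, nonsense records) within
95% binomial confidence limits. These sizes keep a full run in the low
minutes on one core while leaving the binomial checks well-powered.

# Known limitations

* Genomic (`g.`) HGVS is parsed but not normalized beyond parsing; RNA
  (`r.`) syntax and allele/mosaic bracket syntax are not supported.
* Structural variants, breakends and symbolic alleles are out of scope.
* The comparator's equivalence closure is a documented, rule-tagged
  approximation of "transformable by applying the recommendations"; the
  tags make it auditable, but it is not a proof system.
* N-terminal extensions and selenocysteine are not modeled.
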