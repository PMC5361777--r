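---
title: "Methods: comparative protease-inhibitor repertoire analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative protease-inhibitor repertoire analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tickPI)
```

## The problem

Hard ticks express large repertoires of protease inhibitors (PIs) that
regulate their own physiology and manipulate host defences (blood clotting,
platelet aggregation, inflammation) during multi-day feeding. Cataloguing
these repertoires — how many distinct PIs a species carries per MEROPS-style
inhibitor family, which of them are expressed in which sex, feeding state or
tissue, and which are conserved across tick species — is the first step in
prioritising anti-tick vaccine antigens: families with many near-identical
members suggest functional redundancy (a poor single target), while small,
highly conserved families suggest non-redundant functions shared by all
ticks.

tickPI implements that comparative analysis as a reusable, fully tested
pipeline: family assignment, redundancy collapse at 95% identity,
condition-wise presence/absence repertoire matrices, catalytic-type rollups,
and a cross-species conservation screen at 50% identity. A synthetic-data
generator with machine-readable planted truth stands in for the original
transcriptome and database downloads so every stage can be verified
end to end.

## The procedure

1. **Family assignment** (`assignFamilies()`). Each protein record is placed
   into one of 18 inhibitor families (I1 Kazal, I2 Kunitz, I4 serpin, I8 TIL,
   I21 secretogranin, I25 cystatin, I29 CTLA, I31 thyropin, I32 IAP, I35
   TIMP, I39 alpha-2-macroglobulin, I43 oprin, I51 PEBP, I53 madanin, I63
   pro-MBP, I68 TCI, I72 chimadanin, I74 variegin) by two rules applied in
   order: a *motif rule* (all of a family's diagnostic motifs present) and an
   *identity rule* (best global identity to an annotated reference member,
   accepted only strictly above 95%). Records matching neither rule — or
   matching several families' motif sets equally well — are `UNASSIGNED` and
   excluded downstream, mirroring the practice of eliminating sequences whose
   family membership cannot be verified.

2. **Redundancy collapse** (`dedup()`). Within one species and family,
   sequences at ≥ 95% identity are deemed redundant and only one is
   retained. Clustering is greedy and longest-first (the CD-HIT convention):
   records sorted by descending length seed clusters in order, and each
   record joins the first cluster whose representative it matches at or
   above the threshold. The retained representative is the cluster seed —
   the longest, hence most complete, sequence.

3. **Repertoire matrices** (`buildRepertoireMatrix()`). For each two-sided
   condition axis — female vs male, fed vs unfed (whole-body libraries),
   salivary gland vs midgut — each family's non-redundant clusters are
   partitioned into left-exclusive, right-exclusive and shared counts. A
   cluster is "present" in a library if *any* of its redundant members was
   observed there (membership union). `reportRepertoire()` assembles the classic
   one-row-per-family report with a totals row.

4. **Catalytic rollup** (`catalyticRollup()`). Family counts are summed into
   the protease catalytic types their members inhibit: serine (I1, I2, I4,
   I8, I21, I51, I53, I72, I74), cysteine (I25, I29, I31, I32), metallo
   (I35, I43, I63, I68) and non-specific (I39, the
   alpha-2-macroglobulins).

5. **Conservation screen** (`screenConservation()`). Each focal-species
   cluster representative is aligned locally against same-family records of
   every other species; the best hit per (query, species) pair is retained
   when its identity is ≥ 50%. `conservationSummary()` bands each query's
   best identity (≥ 80, 65–80, 50–65), the style in which cross-species
   conservation of a family is usually described.

## Alignment engine and identity conventions

All similarity decisions run through one exact affine-gap dynamic program
(compiled code; Needleman–Wunsch for global mode, Smith–Waterman for local),
replacing the interactive BLAST/workbench steps of the original analysis.
Defaults are the classic protein-search parameterisation: BLOSUM62 with gap
open −11 and gap extend −1, where a gap of length $L$ costs
$\text{open} + (L-1)\cdot\text{extend}$. Substitution matrices in the
standard NCBI text format can be supplied via `readSubstitutionMatrix()`.

Identity is `matches / denominator`, reported to one decimal (ties round
up), and the denominator is chosen per decision because the source
publications rarely state one:

* **Redundancy (≥ 95)** uses *global* alignment with the
  *shorter-sequence* denominator. Rationale: transcriptome assemblies are
  full of fragments; a fragment of a transcript should collapse onto its
  full-length original, which the columns denominator would prevent (end
  gaps inflate it).
* **Annotation by identity (> 95, strict)** uses the same convention. The
  two thresholds differ deliberately: redundancy is "95% or greater" while
  annotation-by-identity is "greater than 95%", and each is honoured where
  it applies; a best reference identity of exactly 95.0 does *not* annotate.
* **Conservation (≥ 50)** uses *local* alignment with the *columns*
  denominator, approximating the identity a translated search (BLASTX-style)
  reports over its aligned region.

`X` (unknown residue) scores 0 against everything and never counts as a
match, so unresolved positions can neither create nor destroy identity. `*`
(stop) is treated the same way; stops terminate open reading frames during
six-frame translation, and nucleotide contigs are converted to protein by
taking the longest stop-free stretch across all six frames
(`longestOrfProtein()`), ties resolved by frame order then leftmost start —
a deterministic proxy for what a translated search would effectively score.

Traceback ties resolve diagonal, then up, then left, so every alignment —
and therefore every downstream table — is bit-identical across runs and
platforms. Degenerate cases are defined, not crashed on: an all-negative
local comparison has zero aligned columns (and percent identity is an error
there, surfaced as "no hit" by the screen); empty inputs to `dedup()` yield
an empty cluster list; empty subject sets yield empty hit tables.

## Thresholds and tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `redundancy_identity` | 95 (inclusive) | % identity | the published redundancy rule |
| `annotation_identity` | 95 (strict >) | % identity | the published annotation rule |
| `conservation_identity` | 50 (inclusive) | % identity | the published homolog-retention rule |
| `gapOpen` / `gapExtend` | −11 / −1 | score | classic BLOSUM62 search defaults; the sources name no parameters |
| `minMotifHits` | all motifs of the family | count | demanding every diagnostic motif keeps false assignment negligible |

All of these are configurable per run (`readPipelineConfig()`, CLI flags).

## The diagnostic motifs are heuristic stand-ins

Real family assignment in the original analysis used a curated conserved-
domain database, which cannot be shipped or queried here. The default
`FamilyModel` motifs are therefore simple consensus-style patterns (mostly
literal 6–7-mers, cysteine-flavoured for the disulfide-stabilised families;
I72 has none and is identity-only, since chimadanin shows no conserved
domain). They are explicitly *not* curated domain definitions: their false-
positive rate on random sequences is measured in the test suite (≤ 5% on
1,000 shuffles, in practice essentially zero for literal patterns of this
length), and real-data users are expected to override them — and to supply
annotated reference FASTAs — through the family-model YAML config
(`readFamilyModels()`).

## What the synthetic generator emulates — and what it does not

`generateScenario()` plants, per species and family: a family ancestor
carrying the family's motifs; cluster ancestors mutated from it on
*disjoint* position blocks, which pins any two clusters of a family at or
below the inter-cluster identity ceiling (default 80%); and cluster members
mutated from their ancestor at the intra-cluster identity (default 98%),
some as C-terminally truncated fragments. Because intra-identity > 95 >
inter-ceiling, greedy clustering provably recovers the planted partition
(and equals single-linkage clustering) for any input order — the test suite
checks this over 20 seeds and 50 permutations. Homologs are planted across
species at 40/55/70/85% identity, avoiding the 47–53 guard band so the 50%
retention decision is never a coin flip. Library memberships are drawn per
cluster over a study-like design: whole-body female/male × fed/unfed plus
female salivary-gland and midgut libraries at 48, 96 and 120 h (presence
probability 0.5 per library — a round, uncommitted default for a quantity
the sources do not report).

Mutations are substitution-only, which makes every planted identity exact by
construction; note that the optimal affine-gap alignment of such a pair can
recover an identity up to about 1.5 points *above* the planted value by
gaining extra matches through gaps, so planted identities are verified to
±2 points. Indel robustness is exercised separately by a small hand-built
fixture with internal deletions and truncations
(`inst/extdata/synthetic_indel_variants.fasta`).

The generator deliberately does **not** emulate: codon usage or any
nucleotide-level realism, transcript abundance (the analysis is
presence/absence by design), assembly artifacts such as chimeras,
domain-level architecture beyond the planted motifs, or phylogenetic
structure among species (cross-species background identity is that of
random sequences, ~30–40% over short local stretches). Green tests therefore
demonstrate the pipeline's arithmetic and decision rules, not performance on
real assemblies, where family models and reference sets do the heavy
lifting.

## Printed-table arithmetic and a note on totals

The package ships a transcription of the published per-family repertoire
table for *Amblyomma americanum* (`inst/extdata/repertoire_table_a_americanum.tsv`)
and the published global per-family catalogue counts
(`inst/extdata/global_family_counts.tsv`) as worked-example inputs.
Published tables are not always internally consistent: in this one, the
printed totals row differs by 1–2 counts from the column sums of its own
family rows (two footnoted families were imported from earlier single-tissue
analyses, which explains part of it). `readRepertoireTable()` therefore
preserves the printed totals row verbatim, and `marginalTotal()` is defined
on the totals row — for every matrix the package *computes*, the totals row
equals the column sums (a validity invariant), so the two definitions
coincide; for transcribed tables the printed arithmetic is reproduced as
printed. The package reports its own internally consistent sums everywhere
else and does not attempt to repair the source's aggregates.

Similarly, the published catalytic-type percentages are reproduced from the
printed *per-family component counts* (e.g. the cysteine share is the sum of
the four cysteine-family counts over the catalogue total), which is the
arithmetic consistent with the printed percentages.

## Problem sizes used by the test suite

The suites run on one CPU in a few minutes: exhaustive-enumeration alignment
oracles at lengths ≤ 5 (global) and ≤ 4 (local); an independent
library-implementation oracle on 200 random pairs of length ≤ 8 in both
modes; 20 generator seeds and 50 input permutations for cluster recovery;
a 3-species, 6-family, 48-cluster scenario (~100 records of length 240) for
the end-to-end truth-equality and byte-determinism checks. These sizes were
chosen so the whole suite exercises every decision boundary while staying
fast enough to run on every change.

## Known limitations

* Motif models are heuristic; on real data, assignment quality is bounded
  by the reference sets and motif definitions the user supplies.
* The conservation screen reports best hits per species, not orthology; no
  E-values or alignment statistics are computed, only identity.
* Presence/absence is qualitative. No differential-expression statistics
  are attempted — the underlying comparisons need qRT-PCR-style validation
  before biological conclusions are drawn.
* All-vs-representative greedy clustering is exact under the separation
  conditions the generator guarantees; on real data with identity values
  straddling 95%, greedy and single-linkage results can differ, and the
  longest-first convention is then a (documented) choice, not a theorem.
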