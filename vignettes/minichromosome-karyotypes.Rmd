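---
title: "Methods: comparing fragmented mitochondrial karyotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing fragmented mitochondrial karyotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minikaryo)
```

## The biological model

Sucking lice (Anoplura) have fragmented mitochondrial genomes: the 37
genes typical of bilaterian mitochondria are distributed over 9–20 small
circular minichromosomes, each carrying a coding region (usually one
protein-coding or rRNA gene plus zero to a few tRNAs) and a non-coding
region (NCR) with a conserved AT-rich motif upstream and a GC-rich motif
downstream of the coding region. The assignment of genes to
minichromosomes, their order, and their transcription orientation relative
to the NCR form the mitochondrial *karyotype* of a taxon. Karyotypes evolve
by minichromosome split (fission), merger (fusion), tRNA translocation, and
occasionally gene loss or duplication.

`minikaryo` models karyotypes explicitly and treats *missingness as data*:
short-read assemblies routinely fail to recover some genes (especially
tRNAs and AT-rich `nad6`), so every karyotype declares the genes that were
not identified, and all downstream logic scores those genes as
*unscorable*, never as absent. This is what makes inferred event counts
lower bounds ("at least three splits") rather than point estimates.

## The two-clause parsimony rule

Characters are extracted from karyotypes at two granularities:
co-membership blocks (singletons and pairs of genes resident on one
minichromosome, order- and orientation-insensitive) and oriented
adjacencies (consecutive gene pairs with orientations). Pairs are the
atomic multi-gene form; named blocks like `E-cob` or `K-nad4` are pair
blocks, and larger blocks emerge at assembly time as connected components.
Gene matching is paralog-tag sensitive (`W1` is not `W`), because tag
identity is precisely what distinguishes a duplicated tRNA from its
original.

A character is ancestral to a clade if (1) it is present in at least one
ingroup taxon and in the previously inferred MRCA karyotype of the
enclosing clade, or (2) it is present in every ingroup taxon in which it is
scorable. Three implementation decisions deserve record:

* **Clause-2 denominator.** Taxa in which a constituent gene is missing are
  excluded from "all taxa". We additionally require the character to be
  scorable in a *majority* of the ingroup. Without this floor, a character
  whose genes are identified in a single taxon is vacuously "present in all
  scorable taxa" and would be inferred ancestral — trnC, identified in only
  one of the five seal lice, would be placed, although its position in four
  of five taxa is simply unknown. The floor keeps clause 2 meaning what it
  says while preventing vacuous inference.

* **Placement semantics.** Protein-coding and rRNA genes (*anchors*) are
  placed on singleton support: an anchor present in the ingroup and the
  MRCA defines a minichromosome even when no neighbour can be attached
  (`cox2` alone is itself the evidence of a split). tRNAs are placed only
  through multi-gene characters: a singleton says a tRNA exists, not where
  it is, and "position and arrangement" is what ancestral inference claims.
  Consequently the unplaced set is exactly: genes never identified in the
  ingroup plus tRNAs with no conserved context.

* **Assembly, order and conflicts.** Ancestral characters define a graph on
  genes; connected components become ancestral minichromosomes. Order and
  orientation within a component follow the first source (outgroup MRCA
  first, then ingroup taxa) that carries the whole component on one
  minichromosome, with the most frequent arrangement winning and the
  outgroup breaking ties. A component never observed complete falls back
  to the largest partial backbone and is flagged (`partial_order`
  attribute) rather than silently ordered.

## Event calling

Events are anchored on protein/rRNA genes; tRNAs are too mobile to define
chromosome identity. On a branch from ancestor A to descendant D:

* **Split** — one ancestral minichromosome whose anchors occupy two or more
  D minichromosomes; a k-way split counts once. An anchor in D's missing
  set never vetoes a split: an ancestral minichromosome with one identified
  and one unidentified anchor is counted (this reproduces the
  `D-Y-cox2-nad6` split inferred although `nad6` was never assembled).
  A D minichromosome carrying only tRNAs, all derived from a single
  ancestral minichromosome whose anchor persists elsewhere, is a fission
  product and also records a split — the `cox3-A → cox3 + A` case, where
  the separated part has no anchor. A tRNA-only minichromosome of mixed
  origin is a set of translocations instead.
* **Merger** — one D minichromosome carrying anchors from two or more
  ancestral minichromosomes; counted once per D minichromosome.
* **Translocation** — a tRNA whose anchor context changed, excluding tRNAs
  riding along with a detected split/merger.
* **Loss** — an ancestral gene absent from D and *not* declared missing.
  Paralog emergence is a duplication note, never an event.

Over a phylogeny, each karyotyped node is compared against its nearest
karyotyped ancestor, so events on an unsampled stem accrue once to the
compound branch — this is how the three seal-louse stem splits are
assigned to the stem rather than once per species.

## Alignment identity

`global_identity()` is a Gotoh affine-gap Needleman–Wunsch (Rcpp) with a
ClustalW-style DNA scheme: +1.9 for an identical unambiguous match, 0 for a
mismatch, ambiguity codes scored as the mean over their expansions, gap
open 15, gap extend 6.66, a gap of length L costing `open + L*extend`.
Identity is identical columns over the alignment length, by default
counting internal but not terminal gap columns (`count_terminal_gaps`
switches the dialect; published identities rarely state which was used, so
comparisons to published values carry a ±2 percentage-point tolerance).
The DP is verified against an exhaustive enumeration oracle on all
alignments of short pairs.

The mismatch score of 0 makes the global scheme unusable for local
(maximal-segment) alignment — extension is never penalised — so
`degenerate_scan()` defaults to a symmetric +1.9/−1.9 matrix, under which
segment growth is profitable only above 50% identity. Scans report 1-based
inclusive reference coordinates. Two properties follow from
maximal-segment semantics and are reflected in the tests: a remnant
abutting the reference start maps to nucleotide 1 exactly, while an
interior segment may absorb a few chance-match columns at its flanks.

## Motif discovery

The published motifs were found "by sequence alignment", with no algorithm
stated, so the design here is the package's own: deterministic k-mer
seeding (k = 8; the exact 8-mer shared by the most NCRs, ties to the
lexicographically smallest), approximate recruitment of the remaining NCRs
(Hamming budget from `min_identity`), column-wise extension while the new
column's consensus agreement stays at or above `min_identity`, then one
relocation pass: the provisional consensus is slid over every NCR and each
copy re-anchored at its minimum-mismatch offset, followed by re-extension.
Relocation matters because an AT-rich seed recurs by chance in the AT-rich
background (~70–85% AT), and a misplaced copy would otherwise truncate the
window or corrupt positions. Defaults: `min_coverage` 0.8 and
`min_identity` 70 (both must be tunable — published reports include motifs
in *all* minichromosomes but also partial cases, e.g. GC motifs in only 5
of 12 minichromosomes of the sea lion louse, and a species with no
detectable AT motif at all); `min_length` 20 bp, just below the shortest
published louse motif (25 bp), rejects the short pseudo-conserved windows
that arise by chance among AT-biased random sequences. Because boundaries
are defined by the conservation threshold, published motif lengths are
matched within tolerance (±10% in the planted-motif benchmark), not
exactly.

## The simulator: a stated world

The generator exists so every stage is testable without downloads. Its
defaults encode the regime the comparative analysis describes: roughly 11
ancestral minichromosomes; splits several times more frequent than mergers
(defaults 0.3 vs 0.08 expected events per branch); tRNA translocations in
between (0.2); loss off by default; NCRs of 200–320 bp (default 300) at
~70% AT with planted motifs of 56 bp at 85% AT and ≤5% per-copy noise —
all values taken from, or bracketed by, the published per-species reports.
Event rates are per *branch* (karyotype evolution in lice is too episodic
for a clock), while sequence divergence scales with branch length:
substitutions per site are Poisson and each event redraws the base
uniformly, giving the closed form `P(match) = exp(−2d) + (1 − exp(−2d))/4`
for two tips at per-lineage divergence d, which the tests check at 3σ.
With `detectable = TRUE` (default) splits cut between anchors and only
anchor-bearing minichromosomes merge, so that on clean histories the
ground-truth log is exactly recoverable by `detect_events()`; under higher
rates events mask one another and detected counts are bounded above by the
truth, never inflated.

What a green simulator test does *not* establish: recovery from real
short-read assembly artefacts (chimeric contigs, partial genes), realistic
indel processes in NCRs, heterogeneous substitution models, or tRNA
identity confusion between near-identical paralogs. The simulator is a
correctness harness, not a realism claim.

## Fixtures and their provenance

The packaged karyotypes of the five seal lice and the gorilla louse
transcribe every published statement about them (minichromosome counts,
identified/missing gene lists, named minichromosomes, orientation
exceptions, split/merger anchors). The published per-species text is,
however, internally inconsistent for the two *Antarctophthirus* twins: 30
identified genes (14 of them protein/rRNA anchors) cannot occupy nine
minichromosomes at one anchor each. The fixtures keep the audited printed
counts and place the excess anchors on shared minichromosomes; every such
synthetic placement is confined to arrangements the text leaves open, is
declared in the fixture's `#source` header, and those two tips are
excluded from the event tally (their synthetic anchor pairings would
otherwise register as mergers no publication claims). The same applies to
the 17th gorilla-louse minichromosome and to the wholly synthetic
supporting karyotypes (primate-louse MRCA, pig louse, macaque louse),
which encode only the published merger topology. The sucking-louse MRCA
karyotype is consumed as an input fixture and never recomputed.

## Numerical and determinism choices

All canonical orderings (minichromosome labels, character ids, event
tables) use byte-wise (C-locale radix) sorting, so outputs are
byte-identical across locales and reruns; the pipeline's idempotence is
tested. Ties in consensus columns break by fixed base order A<C<G<T; ties
in arrangement frequency break toward the outgroup. The aligner's
tracebacks prefer match over gap-in-first over gap-in-second at equal
score. All randomness flows through R's RNG from a single seed recorded in
the simulation config.

## Known limitations

* The full published census (15–16 splits across 21 species in six
  families) requires karyotypes from six prior papers that are not printed
  in the transcribed source; the tally here covers the encoded lineages
  (where merger occurred exactly four times).
* Identity values tied to deposited GenBank sequences (trnW paralogs,
  inter-species gene identities, degenerate-gene percentages) cannot be
  reproduced offline; the operations are implemented and validated on
  synthetic data and exhaustive oracles instead, and the corresponding
  acceptance checks are left red rather than approximated.
* Ancestral inference reconstructs one user-named clade at a time against
  a supplied outgroup MRCA; simultaneous all-node reconstruction and
  probabilistic models are out of scope.
* Circularity of minichromosomes is not modelled beyond storing flanking
  NCR strings; gene order is linear from the upstream (AT-motif) end.
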