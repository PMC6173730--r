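---
title: "Pseudochromosome construction from synteny and genetic-map anchors"
author: "ChromAnchor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudochromosome construction from synteny and genetic-map anchors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ChromAnchor)
```

## The problem

A long-read de novo assembly of a plant genome typically ends at the contig
stage: hundreds to thousands of sequences, each from a single chromosome
region, but with no information about which chromosome they belong to, in
what order, or in what orientation. When a chromosome-scale reference of a
closely related species exists together with a genetic map for the target
species, both can be turned into *anchor points* — correspondences between
a position on a contig and a position on a chromosome-scale coordinate
system — and the contigs can be arranged into pseudochromosomes without
any additional sequencing. ChromAnchor implements this two-map strategy
end to end for the case of a wild rice relative anchored against a
domesticated-rice reference, together with the companion analyses that
typically accompany such an assembly project: haplotype-variant
classification, collinear gene chains with synonymous rates, and windowed
functional enrichment.

Two maps feed the scaffolder:

* **Synteny map.** Reference gene models (first isoform per gene) are
  aligned to the contigs; the best hit per gene (maximal bitscore, ties by
  longer alignment then lexicographic subject) ties a contig position to
  the gene's start coordinate on its reference chromosome. Isolated hits
  to a foreign chromosome — a run of length 1 in the contig-ordered hit
  list, on a contig with at least three hits — are the signature of a
  paralogous alignment and are removed (`filterSpuriousRuns()`). For
  contigs with a single surviving hit, both the gene start and gene stop
  coordinates become anchors, so even a one-gene contig can be oriented.
* **Genetic map.** Each SNP marker is represented by a 200 bp flank
  sequence aligned to the contigs. A marker anchors a contig only when its
  placement is unambiguous: one best alignment at ≥ 95% identity, with no
  secondary alignment within 10 bitscore units (near-repeats disqualify).
  The anchor sits at the SNP position itself (flank offset, strand-aware),
  and carries the marker's centimorgan position.

All internal coordinates are 0-based half-open; GFF3, AGP and 12-column
alignment tables are converted at the boundary in both directions.

## Chimera detection and splitting

A chimeric contig joins sequence from two chromosomes. With both maps
pooled per contig and ordered by contig position, such a contig shows two
long runs of anchors labelled with different linkage groups. Runs of at
least `chunk = 4` anchors are considered supported; shorter runs are
transparent — they are skipped when looking for a conflicting neighbour
but never merge the runs around them, so a lone mislabelled anchor inside
a long run cannot mask or create a breakpoint. Each adjacent pair of
supported, disagreeing runs yields one breakpoint at the midpoint
(rounded down) between the flanking anchors; the contig is cut there, its
parts renamed `<id>_part1`, `<id>_part2`, …, and **both maps are rebuilt
on the split contigs** before any placement decision is made. Conflict is
defined as linkage-group disagreement only: large jumps of map position
within one group do not split a contig, because within-group distance is
confounded by the very rearrangements the assembly is meant to reveal.

## Assignment, ordering, orientation

Each contig is assigned to the linkage group holding the strict majority
of its weighted anchors (per-map weights default to genetic = 1,
synteny = 1 and are configurable); exact ties and anchor-free contigs go
to the unplaced pool.

Within a linkage group, centimorgan and base-pair positions are not
commensurable, so each map's positions are first converted to normalized
ranks in (0, 1). A contig's position score is the weighted mean of its
anchors' normalized ranks, and contigs are sorted by ascending score
(ties: longer contig first, then lexicographic id). This score is a good
global estimate but has a known blind spot: the two maps sample the
chromosome at very different densities (tens of markers versus hundreds
of genes), so a quantile from one map and a quantile from the other may
disagree by more than the spacing of two adjacent contigs. A
deterministic refinement pass therefore follows the initial sort:
adjacent contigs are swapped while the swap strictly reduces the weighted
number of discordant anchor pairs, counted *within each map separately*
(where order comparisons are exact). Because the discordance count is
non-negative and strictly decreases with every swap, the pass terminates;
when the anchors are noise-free it can only stop at the true order, since
any misplaced adjacent pair is discordant in at least one map and
concordant in none.

Orientation follows the same within-map principle: for each map with at
least two anchors on the contig, the weighted rank correlation between
contig positions and map positions is computed, and the per-map
correlations are combined weighted by map weight × anchor count. A
negative combined sign flips the contig; zero correlation or a single
anchor defaults to "+".

Pseudomolecules are emitted with 100 bp N-gaps between placed contigs (a
conventional fixed scaffold-gap size; the maps carry no gap-length
information) and all unplaced contigs concatenated into one pool sequence
with 1 kb separators, large enough that the pool can be unambiguously
re-split. AGP 2.1 rows (gap rows: `scaffold`/`yes`/`map`) describe both,
and reconstruction from AGP plus contigs is tested to reproduce the
emitted sequences base for base.

## Haplotype variants

Small and large variants live in disjoint regimes separated at 10 bp.
Small variants (REF and ALT both ≤ 10 bp) are binned at 1 Mb and
expressed as variants per kb of each feature class (CDS, locus, 1 kb
upstream — derived strand-aware from the loci and clipped at chromosome
edges — and repeats); bins without feature bp are dropped, bins with
feature bp but no variants count as zeros in the per-class median.

Large variants are inferred from consecutive alignment blocks of the same
(reference, query, strand) pair, walked in query order. With R the signed
reference gap and Q the signed query gap (negative values are overlaps),
the class follows the standard between-alignment sign table: Q > R gives
insertion (R ≥ 0), repeat expansion (R < 0 ≤ Q) or tandem expansion
(Q < 0); Q < R gives the mirrored contraction classes; Q = R carries no
event. The size is |Q − R|. A call is kept only when max(|R|, |Q|) > 10 —
the retention filter is applied to gap magnitudes, since a negative gap
records an overlap whose size, not sign, is what the field reports — and
when the size is at most 10 kb (beyond that, a gap between blocks is an
alignment break, not a variant; the cap is configurable). Swapping the
two haplotypes' roles exactly mirrors every class count, which the test
suite exercises on random alignments.

## Collinear chains and Ks

Cross-genome gene matches are chained in rank space (gene order, not bp):
a dynamic program extends a chain when both rank gaps are positive and at
most `maxGap = 20`, paying one unit per skipped rank per axis, and
negative-scoring prefixes are dropped. Match scores are
min(50, −log10 e-value). Chains are extracted greedily by descending
chain score with one-to-one match membership — a deterministic,
reproducible stand-in for arbitrary overlap resolution — inverted chains
are found by negating one rank axis, and chains shorter than
`minPairs = 5` are discarded. The test suite checks the program against
exhaustive enumeration of all valid chains on small random instances.

Synonymous rates use Nei–Gojobori (1986) counting with the Jukes–Cantor
correction. Synonymous site counts per codon are averaged over the two
sequences; codons differing at several positions average their synonymous
difference counts over all substitution orderings, excluding pathways
through stop codons (if every pathway is blocked, all orderings are
used). pS = Sd/S and Ks = −¾·ln(1 − 4/3·pS); pS ≥ ¾ is reported as a
saturation flag rather than a number, as are pairs that violate the
preconditions (unequal length, frame, internal stops). Pairs are consumed
pre-aligned: codon-aware alignment and maximum-likelihood substitution
models are out of scope, NG86 serving as the standard rank-preserving
proxy for colouring syntenic dotplots and separating recent orthologues
from ancient duplicates.

## Windowed enrichment

Chromosomes are tiled into non-overlapping 0.5 Mb windows (the last
window truncated). Each gene belongs to the window containing its start —
under half-open tiling this assignment is tie-free. For every
(window, category) pair with at least one member, a one-sided Fisher's
exact test asks whether the category is over-represented among the
window's genes; the one-sided default reflects that the scan targets
enrichment (a `two.sided` switch exists, which would also flag
depletion). All tested pairs form a single Holm family — correcting per
window or per category would control a different, weaker error rate than
the genome-wide scan implies. Significance is adjusted p ≤ 0.05. The
implementation's p-values are tested against direct hypergeometric
enumeration, and the Holm adjustment against its step-down definition.

## The simulator

`simConfig()` fixes the study conditions: 4 chromosomes × 200 genes
(1 kb genes, 2 kb intergenic spacing, so 602 kb per chromosome), 80
contigs, 30% of contigs inverted, 3 cross-chromosome chimeric joins, 60
markers with centimorgans proportional to position (20 kb/cM), a 2%
spurious-hit rate and 10% anchor drop-out. These sizes keep a full
simulate–scaffold–evaluate cycle in seconds while leaving ~20 contigs per
chromosome and several anchors per contig, the regime the method is
designed for. Chromosomes are cut at random intergenic midpoints, so
genes are never split; chimera partners are drawn from pieces with at
least 4 genes per side, so every simulated mis-join is detectable in
principle at the default `chunk`. Spurious hits are given bitscores that
beat the true hit of their gene — a spurious alignment that loses best-hit
selection would be invisible downstream, so only dominant ones are
simulated. A single seed drives everything through fixed per-stage
sub-seeds; identical configurations produce bit-identical files.

What the simulator does *not* emulate: repeats (sequence content is
random and never realigned — the toolkit consumes alignment tables, it
does not produce them), read-level errors, realistic marker ascertainment
or nonlinear recombination landscapes, and polyploidy. Passing recovery
tests therefore demonstrate the correctness of the anchoring, splitting,
ordering and orientation logic under the stated noise model — not
robustness to repeat-driven mis-alignment, which enters upstream of this
toolkit.

`evaluateRecovery()` scores a result against the truth: per-chromosome
Kendall tau of contig order, orientation accuracy, chimera breakpoint
precision and recall (a call within one intergenic distance of the truth
counts), bp placement rate, and the fraction of adjacent true pairs
preserved. The adjacency metric conditions on both contigs of a pair
being placed: it measures ordering, while placement loss is already
reported by the placement rate. With no chimeras simulated and none
called, precision and recall are 1 by convention.

## Numerical choices and degenerate inputs

* Best-hit ties: longer alignment, then lexicographically smaller
  subject; ordering ties: longer contig, then lexicographic id; chain
  extraction ties: forward orientation preferred. Everything is
  deterministic; no step uses unseeded randomness.
* Run filtering is single-pass: runs are computed once on the original
  order and removals do not merge flanking runs, so a cascade of
  re-filtering cannot eat a contig from the edges inwards.
* Breakpoint positions round the midpoint down; breakpoints landing at a
  contig boundary are rejected.
* Markers whose SNP offset falls outside the aligned flank span are
  dropped with a warning and counted, not errors — partial flank
  alignments at contig edges are expected.
* Degenerate CDS pairs (length mismatch, frame violation, internal stop)
  and saturated pairs are flagged and excluded from medians, never
  estimated.
* Empty inputs return empty results (empty FASTA, no chains, no tested
  enrichment pairs) rather than errors, except where a computation is
  undefined (N50 of nothing, statistics of an empty contig set).

## Limitations

The scaffolder deliberately replaces the genetic-algorithm path search of
ALLMAPS-style tools with a deterministic rank consensus plus local
refinement: reproducibility and testability against simulator truth were
preferred over heuristic search, and the refinement only explores
adjacent swaps, so a contig whose initial score lands it far from its
true position among similarly scored neighbours may not travel there under
heavy noise. Gap sizes are fixed constants, not estimated from read data.
Within-alignment (base-level) indels are out of scope for the large-variant
caller, whose input blocks carry no base-level detail; small variants
arrive separately as a VCF-like table. Neighbouring syntenic chains are
reported unmerged.
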