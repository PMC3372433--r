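---
title: "Detecting conserved syntenic segments between genetic maps and physical genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conserved syntenic segments between genetic maps and physical genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synmapr)
```

## The problem

Comparative mapping across distantly related plants asks whether the
linkage of loci has survived a hundred million years of chromosome
evolution. One side of the comparison is typically a *genetic map* — a few
hundred single-copy markers with linkage-group (LG) assignments and
positions in centiMorgans — while the other is a *sequenced genome* with
positions in base pairs. The two coordinate systems are incommensurable,
marker density is low (hundreds of markers for hundreds of megabases), and
the genomes differ in chromosome number. `synmapr` implements the classic
answer: reduce markers to single-locus orthologs, then chain them into
conserved syntenic segments (CSS) under explicit distance constraints, and
read conservation off the block structure.

## Ortholog assignment

The assignment cascade turns a BLAST tabular hit file into exactly one
status per marker.

* Hits above the primary E-value cutoff (`e_primary`, default `1e-6`) are
  ignored. A stricter tier (`e_strict`, `1e-10`) is kept for bookkeeping;
  the conserved/absent decision uses `e_primary`, chosen as the balance
  between sensitivity and background for cross-family nucleotide searches.
* Remaining HSPs of a query are merged per subject: HSPs whose midpoints
  fall within `hsp_merge_window` (default 50 kb) of the growing span
  collapse into one locus at the span midpoint. BLAST splits a gene-scale
  match into several HSPs (introns, indels); without merging, every intron
  would masquerade as a second locus. The 50 kb default comfortably covers
  a plant gene plus UTRs while staying far below the distance between
  tandem family members at different loci. The window is a genuinely free
  parameter: no published value exists for it, so it is exposed in
  `cascade_thresholds()` rather than hard-coded.
* A marker with exactly one merged locus is `single_locus` and carries a
  target position (the locus midpoint). More than one locus — including
  exact E-value ties on different chromosomes — means `multi_locus`:
  conservative exclusion, because a marker that may sit at two places
  cannot anchor synteny. Single loci on unanchored contigs or on
  chromosome-known/position-unknown segments are parked under their own
  statuses and likewise excluded from chaining.
* Markers with no primary hit are `absent`, unless a relaxed
  transcript/CDS fallback search (cascade `1e-30`, `1e-20`, `1e-5`)
  finds them, in which case they are `absent_primary_conserved_fallback`.
  Fallback rescues affect conservation tallies only, never synteny input:
  a transcript hit has no reliable genomic position.

The six statuses partition the query universe; `assignment_tally()` always
sums to the number of queries, and relaxing `e_primary` can only move
markers out of `absent` (a monotonicity that the test suite sweeps).

## Threshold derivation

Chaining needs a maximum allowed gap on each coordinate system.

* **Physical:** `derive_physical_threshold(G, N, w)` returns `w * G / N` —
  the span of `w` genes at the target's mean gene density. With the
  grapevine figures (`G` = 475 Mb, `N` = 30,434 predicted genes) a 200-gene
  window is about 3.1 Mb; the operational setting of 3.2 Mb corresponds to
  ~205 genes. A gene-count window, rather than a fixed distance, makes the
  threshold transferable between targets of different compactness.
* **Genetic:** 1 % of the total map length (`derive_genetic_threshold`),
  e.g. 14.63 cM for a 1463 cM map. Whether the derived value is floored to
  an integer (14.63 → 14) is an explicit policy flag of
  `synteny_thresholds(floor_to_int = )`, never silent. For a ~1350 cM map
  the conventional setting is 12 cM, which is close to but not exactly 1 %;
  `synteny_thresholds()` therefore accepts it as an explicit override
  rather than pretending it derives.

## CSS detection

Within each (query LG, target chromosome) pair, single-locus markers are
sorted by map position (co-segregating markers tie-broken by marker id, so
results are deterministic; their mutual gap is 0) and chained greedily
left-to-right: a marker extends the open chain iff its query gap and its
*unsigned* target gap to the previous chained marker are both within
threshold; a violation closes the chain and opens a new one. Chains with at
least `min_markers` (default 3) markers become blocks.

Two design points deserve emphasis:

* **Gaps are unsigned.** The rule is proximity-only; an inverted segment
  chains exactly like a collinear one, and reversing a chromosome's
  coordinates provably leaves block membership unchanged (tested). Block
  detection and inversion detection are different questions; at a few
  hundred markers per genome there is rarely power for the latter.
* **Interspersed markers do not break chains.** Mapped markers inside a
  block's query span whose orthologs lie elsewhere (or are multi-locus or
  absent) are counted per block (`n_interspersed`) but do not reset gaps.
  Real blocks carry a steady trickle of such markers — on the order of a
  few per block — from small-scale rearrangements in either lineage. An
  optional `max_interspersed` break rule was considered and left out of the
  default path: it adds a second, poorly identifiable knob, and the gap
  constraints already bound how much foreign material a chain can jump.

Because greedy chaining only ever breaks at gap violations, its output
equals the exhaustive enumeration of maximal valid chains; the test suite
verifies this identity against a brute-force oracle on 1,000 random
instances of up to 15 markers with `min_markers` in 2–4.

Map-versus-map comparisons (`detect_css_maps()`) use the same chaining with
a cM gap on each axis, each map keeping its own threshold (e.g. 12 cM on a
coffee-like map against 14 cM on a tomato-like one).

`summarize_blocks()` reports the descriptive statistics of one comparison:
block count, mean/max spans on both coordinate systems, markers per block,
interspersed markers per block, and the mean distance between adjacent
syntenic markers. Adjacent-marker distances are *pooled* across all
consecutive member pairs of all blocks rather than averaged per block and
then across blocks; pooling weights every marker pair equally and is the
natural estimator of typical marker spacing inside blocks. Degenerate
input (no blocks) yields a zero summary with `n_css = 0`.

`project_multiway()` triangulates two pairwise comparisons that share a
reference genome: every pair of blocks on the same reference chromosome
gets its target-interval overlap (continuous-length semantics: the overlap
of [1,5] Mb and [3,8] Mb is 2 Mb, the Jaccard index 2/7) and each
chromosome its covered fraction under the union of block spans, flagging
chromosomes untouched by either comparison.

## Microsynteny

At BAC scale the data change character: complete ordered gene lists with
orientations and gene-family labels (families are an *input*, normally
curated from reciprocal sequence comparisons; `families_from_similarity()`
exists only to build fixtures). `align_segments()` computes a collinear
backbone as a longest common subsequence of family labels — one match per
family occurrence, so a tandem array contributes one matched pair and the
extra copies are classed `duplicated`. Matched pairs whose relative
orientation equals the majority relative orientation over the backbone are
`same_order_and_orientation`; the rest are `inverted`. An exact tie in the
majority defaults to the same-orientation frame. Genes without a family
label, or whose family never matches, are lineage-specific. With
`allow_reverse_reading` the reversed-and-flipped reading of the second
segment is tried too and the larger backbone wins (ties keep the forward
reading) — a physical segment has no privileged reading direction.

When several equally long backbones exist, the leftmost-in-A one is chosen
deterministically. A consequence worth knowing: the matched *count* is
symmetric under swapping the segments and invariant under reversal (both
tested, against a brute-force LCS oracle on 500 random pairs of up to 12
genes), but the duplicated/lineage-specific split of the unmatched genes
can differ between equally long backbones, so only per-side totals are
guaranteed to mirror. `overlap_window()` re-runs the classification on
order-index windows — the honest way to compare segments sequenced to
different extents — and can only lose matches relative to the full
segments. `multi_segment_matrix()` produces all pairwise reports; a
three-way pattern such as "conserved between segments 1 and 3 but absent
from 2" is read off the matrix rather than computed by a dedicated
three-way aligner.

The package ships three small synthetic GFF3 segments (coffee-like,
Solanaceae-like, grape-like) whose family structure mirrors the qualitative
situation at a fruit-shape locus: the coffee-like and grape-like segments
share 12 families with a single inversion, the coffee-like and
Solanaceae-like segments only 8 with two inversions and a tandem
duplication. The fixtures encode the *direction* of the contrast; their
exact counts are fixture-defined, not estimates of any real locus.

## The simulator and what passing tests mean

`simulate_ancestor()` lays out point markers on chromosomes with i.i.d.
exponential gaps; `evolve()` runs two (or, via `simulate_trio()`, three)
independent lineages of large-scale rearrangements — inversions and
reciprocal translocations (weight 0.4 each) plus fusions and fissions
(0.1 each, so descendant chromosome numbers drift apart as they do between
real karyotypes) — followed by per-marker loss and paralog insertion.
Breakpoints fall only between markers: markers are points, and sub-marker
breakage is unobservable at map resolution. One descendant is observed as a
genetic map via `project_genetic()`, which converts bp to cM with a locally
varying recombination rate (truncated-normal per inter-marker gap), *rank
preserving* by construction — map noise that reorders markers would make
truth blocks ill-defined, and typing-error-style reordering is deliberately
not part of the default model. The other descendant is observed as a
physical feature table and a hit table (`emit_hits()`): every surviving
ortholog gets one strong hit, paralog copies and optionally planted
spurious hits exercise the multi-locus exclusion, and `emit_fallback_hits()`
models transcript rescues for target-lost markers. All randomness flows
from one integer seed; equal seeds give byte-identical outputs.

Default conditions (the ones the recovery tests and the acceptance script
use): 11 chromosomes × 40 markers, mean physical gap 500 kb, 2 cM/Mb mean
recombination (sd 0.5), 8 rearrangements per lineage, 10 % marker loss,
5 % paralogs. The marker spacing is chosen well inside the 3.2 Mb chaining
gap so that recovery tests probe the chaining logic, not marker sparsity;
at paper-like sparsity (markers ~1.5–2 Mb apart, i.e. comparable to the
gap threshold) blocks fragment for sampling reasons alone, which is a
property of the data, not of the algorithm. Even at the default spacing
the exponential tail puts roughly 0.2 % of adjacent gaps beyond 3.2 Mb,
so the no-rearrangement control occasionally yields one or two blocks more
than the chromosome count at some seeds — a sampling split, not a
detection error.

**True blocks.** The simulator defines a true block as a maximal set of
shared markers that (i) forms a contiguous run in the ancestral marker
order, (ii) lies on one chromosome in each descendant, and (iii) is
uninterrupted in each descendant by other markers of its own
(chromosome-A, chromosome-B) context — markers from *other* contexts may
intersperse it, since those are exactly the interspersed non-syntenic
markers the chaining rule tolerates. This makes an inversion split nothing,
a reciprocal translocation add exactly two blocks, and segments glued
together convergently in both lineages remain distinct. The partition is
computed as a coarsest-partition fixpoint over the three marker orders and
checked in the tests against an independent minimum-parts dynamic program.

**Recovery scoring.** `score_block_recovery()` reports the fraction of
consecutive same-true-block marker pairs (restricted to chaining-eligible,
i.e. single-locus, markers — the orthology cascade is scored by its own
tests) that land in one detected block, and the number of detected blocks
mixing two true blocks. Under the default conditions coverage sits around
95–98 % and false merges at 0–3 depending on the seed.

## Known limitations

* **Convergent junctions are undetectable in principle.** When both
  lineages independently rearrange the same chromosome pair at nearby
  breakpoints, two distinct ancestral segments become adjacent in *both*
  observed genomes; a proximity rule must chain them, and any faithful
  truth set must count that a merge. At 8 events per lineage on 11
  chromosomes this happens at some seeds and not others.
* The chaining rule attaches no statistical significance to blocks; with
  ~3 markers minimum and genome-scale thresholds, small blocks can arise
  by chance and should be read as candidates, not proofs.
* Simulated hit tables are far cleaner than real BLAST output (no domain
  shuffling, no low-complexity cross-hits); the cascade's behavior on real
  data depends on upstream masking choices the package does not model.
* The simulator draws breakpoints uniformly and events independently;
  real karyotypes show breakpoint reuse and lineage-specific rates, so
  recovery percentages here characterize the algorithm, not any real
  clade.

## Problem sizes in the test suite

Unit and property tests run on instances of 2–15 markers (against
exhaustive oracles), recovery tests on the 440-marker default simulation,
microsynteny property tests on 500 random pairs of up to 12 genes, and the
demo pipeline on a 60-marker simulation; the whole suite completes in
about a minute on one core.
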