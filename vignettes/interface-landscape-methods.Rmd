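---
title: "Methods: structural comparison and connectivity of domain-domain interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural comparison and connectivity of domain-domain interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model

Multidomain proteins bury part of each domain's surface in intra-chain
domain-domain interfaces (DDIs). `ddiscape` implements a pipeline for
asking how degenerate the structural space of such interfaces is: extract
interfaces from annotated structures, align pairs of interfaces
non-sequentially, score their similarity, search each interface for its
closest structural neighbour among *structurally unrelated* domain pairs,
and analyse the resulting similarity digraph. Because the full
crystallographic corpus (CATH-classified X-ray structures) is outside the
package's scope, a deterministic synthetic-structure generator supplies
every input; the generator is first-class, tested code, and its ground
truth is what the test suite and the acceptance script measure against.

## Interface definition

Two residues from different domains are in contact when any heavy atom of
one lies within 4.5 Å of a heavy atom of the other (inclusive boundary;
hydrogens never count). All residues participating in at least one contact
form the interface; its size `L` counts both sides. A domain pair is
*interacting* when `L >= 20`. Both thresholds live in `ddi_params()` and
are applied uniformly by `build_interface()` and `is_interacting_pair()`.
Residues lacking a Cα still count toward `L` (the contact definition does
not need a Cα) but are excluded from alignment coordinates.

Neighbour search prunes candidate residue pairs by centroid distance plus
per-residue bounding radii before exact atom-atom evaluation; tests assert
exact agreement with the all-pairs double loop.

## Topology classification

A domain is *continuous* iff its delineation has exactly one sequence
segment. Two continuous domains are *consecutive* when no classified
domain lies between them and, **only if the intervening linker contains
unresolved residues**, the linker spans at most 13 positions by author
numbering. The restriction of the cutoff to linkers with missing residues
follows the stated motivation for the rule (guarding against an unobserved
intervening domain); applying it to fully resolved linkers as well is
available via `ddi_params(linker_rule_resolved = TRUE)`. Missing residues
are inferred from author-numbering gaps merged with REMARK 465 records —
no other recipe is available from coordinates alone.

A discontinuous domain is represented by its longest segment provided that
segment has at least 100 resolved residues, covers at least half the
domain, and contributes at least 20 residues to the interface
(`select_major_segment()`); otherwise the pair is dropped from the
discontinuous dataset.

## Interface alignment and IS-score

The similarity of two interfaces is scored by

- `S = (1/L_Q) * sum_i f_i / (1 + d_i^2 / d0^2)` over aligned residue
  pairs, where `d_i` is the Cα distance of pair *i* under the alignment's
  superposition and `f_i = (c_i/a_i + c_i/b_i)/2` is the contact overlap at
  that position (`a_i`, `b_i`: contact counts of the template and query
  residues; `c_i`: contacts preserved by the mapping);
- `IS = (S + s0) / (1 + s0)` with `s0 = 0.18 - 0.35 / L_Q^0.3`, making the
  score length-independent with maximum exactly 1 for self-alignment;
- `d0 = 0.7 (L_Q - 15)^{1/3} - 0.1` for non-sequential interface
  alignment and `d0 = 1.24 (L_Q - 15)^{1/3} - 1.8` for sequential
  whole-domain comparison, floored at 0.5 Å where the formulas are
  non-positive (`L_Q <= 15`). `s0` is positive only for `L_Q >= 10`;
  smaller interfaces are rejected as outside the score's regime.

### Search design

The published description fixes the scoring but not the alignment search,
so the search here is the package's own design, validated by oracle
equivalence rather than bit-compatibility with any external program:

- A candidate alignment is a **full per-side one-to-one matching**: each
  query side maps to exactly one template side (both pairings are tried)
  and the matching size is `min` of the side sizes. Its superposition is
  the Kabsch least-squares fit of its own pairs, and its score is computed
  under that superposition. Keeping candidates full-size makes the search
  space identical to the exhaustively enumerable one, so the small-instance
  oracle test compares like with like; the `2*d0` pairing cutoff shapes the
  assignment cost (distant pairs get a flattened kernel so they do not
  steer the assignment) but never removes pairs.
- Seeds: the four sign combinations of principal-axes superposition, an
  identity-order seed when side sizes match, and Kabsch fits of length-6
  contiguous interface fragments (capped at `max_seeds = 40`, evenly
  subsampled). Each seed is refined by alternating rectangular Hungarian
  assignment per side with Kabsch re-superposition until the geometric
  score changes by less than `1e-4` (at most 50 iterations).
- On instances small enough to enumerate (at most `2e4` combined per-side
  injections), an exact enumeration over all assignments is additionally
  run in compiled code and the global best of exact and heuristic results
  is returned.
- Determinism: identical inputs and parameters give identical output; ties
  keep the first candidate in fixed seed order.

### Whole-domain TM-score

Template libraries must contain only domains structurally unrelated to the
query, assessed by a sequential TM-score below 0.4. The comparison is an
iterated gapless-threading + dynamic-programming alignment (linear gap
penalty −0.6 on the distance-kernel score matrix, up to 40 threading
seeds, 20 refinement iterations) scored with the sequential `d0`. The
score is computed normalizing by each domain's length in turn; the filter
uses the maximum of the two, the conservative direction for declaring two
domains unrelated. Tests assert the search dominates a gapless-threading
oracle and reaches exactly 1 on self-comparison.

## Significance

The reference null distribution for the IS-score is not reproducible here
(its parameters are not published), so significance is calibrated on the
synthetic corpus itself: the per-query best-match IS-scores over decoy
(non-planted) interfaces form the null sample, an extreme-value (Gumbel)
distribution is fitted by the method of moments — best-of-library scores
are maxima, for which the Gumbel family is the natural first-order model —
and `p`-values are the fitted upper tail. The threshold at `p = 0.05` is
exposed and used for the "significant match" calls. With a few dozen null
queries the fitted threshold is stable to within a few hundredths of a
score unit, which is adequate for separating planted matches (IS
typically > 0.6) from decoys (IS around 0.1–0.3).

## Dataset construction

- **Clustering:** greedy CD-HIT-style clustering of domain sequences at
  40% identity (inclusive at the boundary), processing sequences by
  decreasing length and joining the first cluster whose representative is
  close enough. Identity is computed from a global alignment (match 1,
  mismatch 0, affine gaps) as identities over alignment length.
- **Non-redundant pair selection:** for every cluster pair `i < j`,
  entries present in both clusters with different domain numbers are
  candidates; one representative is kept per *domain order* (reversed
  order counts as a distinct pair), ranked by best resolution, then
  longest total length, then entry id. The phrase "highest (best)
  resolution with the longest length" is read lexicographically with
  resolution first; `ddi_params(representative_priority = "length")`
  flips the order.
- **Template libraries:** a pool member enters a query's library only if
  (a) none of its domains shares the query's fold topology, (b) all four
  cross-domain sequence identities are below 25% — a deliberately
  conservative surrogate for a database-dependent E-value criterion, with
  a pluggable predicate for callers who have one — and (c) all four
  cross-domain TM-scores are below 0.4.

## Connectivity analysis

Interfaces form a digraph: an edge points from template `t` to query `q`
when `score[q, t]` meets the IS-score threshold (inclusive; the strict
variant is a parameter because the boundary convention is not otherwise
determined). The quantities reported are the fraction of ordered node
pairs with directed distance at most `k` (`n_k / (N (N-1))`, self-pairs
excluded) and the relative size of the largest strongly connected
component of the `k`-closure. Distances come from igraph's BFS; tests
assert equality with matrix-power reachability and brute-force mutual
reachability on graphs up to 50 nodes. Missing score entries (skipped
alignments) never create edges.

# The synthetic generator

`make_idealized_domain()` builds Cα traces from ideal secondary-structure
geometry — helices with 1.5 Å rise and 100°/residue twist at 2.3 Å radius,
strands with 3.3 Å rise and a backbone zigzag calibrated so consecutive Cα
sit 3.8 Å apart, loops as uniformly spaced circular arcs bulging away from
the element bodies — decorated with pseudo-backbone heavy atoms (N, C
toward the chain neighbours, a Cβ on the outward bisector). Side chains
are not modelled; the 4.5 Å contact rule is applied to these pseudo-atoms
unchanged. Pseudo-Cβ atoms that would clash (< 2.5 Å, non-neighbours) are
pruned, with domain atoms protected over linker decorations.

`make_domain_pair()` places the second domain against the first
face-to-face (approach along the flattest principal direction with random
tilt and spin), slides to the closest clash-free separation and retreats
until the interface size lands within 10% of the target (default
`L = 24`, a mid-sized interface given the 20-residue interacting rule).
Linkers are arc-routed around the complex; a configurable central stretch
of the linker can be left unresolved, producing both a numbering gap and
REMARK 465 records on export. Rigid placement of convex idealized bodies
saturates around 30 interfacial residues, so larger targets (e.g. the
`L = 50` interfaces needed to exercise the discontinuous-domain rules) are
reached by *bridging*: pseudo side-chain atom pairs placed 3.9 Å apart on
the line joining cross-domain Cα atoms, clash-checked against everything
already present, until the target interface size is met. Discontinuous domains are made by inserting
domain B into domain A's sequence, leaving A's structure intact as two
segments.

`plant_similar_interface()` copies an interface's Cα geometry (both sides)
under a random rigid transform plus iid Gaussian noise, grafts it between
freshly generated host domains of a style absent from the source pair
(same-style idealized domains are always structurally similar, TM > 0.7,
while cross-style pairs sit below 0.4, so the hosts are verifiably
unrelated), and adds pseudo side-chain atoms placed pairwise between
contacting residues so the source's contact map is realized structurally
rather than copied as annotation. Ground truth records the full residue
correspondence.

What the generator does *not* emulate: real side-chain packing and
chemistry, loop irregularity, crystallographic noise, fold-continuum
variety (three idealized styles only), or realistic sequence-structure
coupling (sequences are random or family-derived independently of
coordinates). Passing tests therefore demonstrate correctness of the
algorithms under controlled geometry, not performance on PDB data; the
published corpus-level statistics are deliberately not targets.

## Default study conditions

The benchmark suite (`suite_spec()`) fixes the conditions used by the
analysis scripts and tests: 31 decoys, 10 planted entries cycling noise
over {0, 0.25, 0.5} Å, 3 multi-domain, 3 discontinuous (larger interfaces,
`L = 50`, so the major segment can contribute its required 20 residues),
3 missing-linker entries with gaps {10, 13, 14}, pseudo-resolutions mostly
in 1.5–2.4 Å with two entries beyond 2.5 Å to exercise the filter, and two
sequence families at 45% identity. The acceptance checks use 50 generated
entries, 20 planted queries against 50-template libraries, a noise grid of
{0, 0.5, 1, 2, 4} Å with 20 replicates per level, 20 exhaustive alignment
oracle instances (5 residues per side — the largest size enumerable in
reasonable time), 50 random graphs up to 50 nodes, and 20 random
cluster/record instances for the non-redundancy oracle. The acceptance
script scales the corpus to 24 decoys and 12 planted queries with 6
replicates per noise level so a full from-scratch run completes in a few
minutes on one core.

# Numerical choices and edge cases

- Distance boundaries are inclusive throughout (contacts at exactly
  4.5 Å count; clusters join at exactly 40%; digraph edges at exactly the
  threshold).
- Kabsch superposition uses SVD with determinant correction (always a
  proper rotation); degenerate inputs (fewer than 3 points, collinear
  clouds) raise errors rather than returning reflections.
- Assignment ties break toward the lowest query index; enumeration order
  is fixed, so all results are reproducible bit-for-bit under a seed.
- Empty interfaces are flagged objects, not errors; empty template
  libraries yield an explicit empty search result and are counted as
  skipped queries in dataset searches.
- Sample statistics use the n−1 convention.

# Known limitations

- The alignment reports full per-side matchings; partial alignments that
  drop geometrically hopeless pairs could score marginally differently on
  very dissimilar interfaces (they would change `f_res` but barely `S`,
  since far pairs contribute almost nothing).
- The Gumbel null is a parametric smoothing of a modest sample; its tail
  p-values beyond the sample range are extrapolations.
- The three idealized styles bound the structural variety of the corpus;
  fold-level conclusions about real proteins are out of scope by design.
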