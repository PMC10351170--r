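---
title: "Alignment-safe windows from suboptimal alignment spaces"
author: "alignsafe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-safe windows from suboptimal alignment spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alignsafe)
```

## The problem

A pairwise global alignment of two protein sequences is usually reported as
a single optimal solution, but for divergent sequences the score landscape
is flat: enormous numbers of alignments score at, or within a few points
of, the optimum, and the particular optimum a program returns is an
arbitrary pick among them.  `alignsafe` quantifies which *parts* of an
alignment are trustworthy.  An interval of an alignment is **(α, Δ)-safe**
when it appears in at least a proportion α of all alignments whose score is
within Δ of the optimal score.  A maximal such interval is a **safety
window**.  Safety windows typically coincide with the structurally
conserved backbone of the proteins, while the ambiguous stretches between
windows flag regions where the alignment (and often the structural
correspondence) is uncertain.

## The alignment graph

For sequences *A* (length *n*) and *B* (length *m*) under a substitution
matrix *M* and affine gap score gap(ℓ) = p + ℓ·g, the package builds the
standard three-state dynamic-programming DAG: every coordinate pair (i, j)
carries a match-state node C(i,j) and two gap-state nodes D(i,j) (inside a
gap consuming *A*) and I(i,j) (inside a gap consuming *B*), with edges

* C(i,j) → C(i+1,j+1), weight M[A[i+1], B[j+1]] — aligned residue pair;
* C(i,j) → D(i+1,j) and C(i,j) → I(i,j+1), weight p + g — gap opening
  (the open penalty and the first gapped residue are charged together);
* D → D and I → I, weight g — gap extension;
* D(i,j) → C(i,j) and I(i,j) → C(i,j), weight 0 — gap close.

A length-ℓ gap therefore accumulates exactly p + ℓ·g.  Paths from
s = C(0,0) to t = C(n,m) correspond to global alignments; the heaviest path
weight is the optimal score OPT.  Prefix scores r\*(v) (best s→v weight) and
suffix scores w\*(v) (best v→t weight) are computed by one sweep per
direction in topological order.

The **Δ-suboptimal subgraph** keeps an edge e = (u, v) exactly when
r\*(u) + w(e) + w\*(v) ≥ OPT − Δ, i.e. when some alignment of score at
least OPT − Δ crosses it.  This is the smallest subgraph containing every
Δ-suboptimal path.  It can also contain s–t paths *below* OPT − Δ
(combinations of good prefixes and good suffixes that do not meet); the
package, like the method it implements, computes proportions over all s–t
paths of the subgraph.  `oracle_safety_windows(mode = "suboptimal")`
enumerates only the truly Δ-suboptimal paths on small instances so the
effect of this approximation can be measured; on the random small instances
used in the tests the two modes almost always coincide, and the spurious
paths carry weight penalties of at least one extra gap opening, which makes
them rare for Δ below |p|.

## Exact counting and safety

For every node the package counts the s→v and v→t paths of the subgraph
(`count_paths()`).  The proportion of s–t paths through an edge (u, v) is
d_r(u)·d(v)/d(s); through a contiguous subpath (v₁…v_k) it is
d_r(v₁)·d(v_k)/d(s).  These counts grow like the Delannoy numbers
(≈ 5.8ⁿ), far beyond what 64-bit integers or doubles can represent
exactly, so all counts are kept in an arbitrary-precision integer
representation (base-10⁶ limb vectors) and every threshold test
"proportion ≥ α" is evaluated as the exact integer comparison
den·d_r·d ≥ num·d(s), with α = num/den taken from its printed decimal.  A
double-precision shadow of the count tables is used purely as a
conservative prefilter: only comparisons within 0.05 of the boundary fall
through to big-integer arithmetic, and every accept/reject decision is
exact.  Results are independent of evaluation order.

For α > 0.5 any two α-safe items are crossed by more than half of all
paths each, so they share a path; consequently a single spanning s–t path
P\* contains every α-safe subpath.  The package requires α ∈ (0.5, 1]
(below that threshold the safe paths need not be totally ordered and the
windows would not be intervals of one alignment).  P\* is constructed by
collecting the α-safe *edges* and also the α-safe *nodes* — a maximal safe
subpath can be a single node whose incident edges are all below α — sorting
them by the topological key (i + j, gap states before C), and stitching
consecutive anchors with a deterministic search restricted to the rectangle
between them.

Safety windows are then found by a two-pointer sweep along P\*: the right
pointer visits each node, the left pointer advances minimally until the
interval is α-safe, and an interval is emitted when it is also
right-maximal.  Every reported window satisfies p ≥ α while both one-node
extensions fall below α; windows have strictly increasing endpoints, and
subpaths whose projections are empty on both sequences (pure gap-state
transitions such as a lone close edge) are discarded before output.

## Coordinates and projections

Window endpoints are *between-characters* coordinates: the node grid is
{0..n} × {0..m}, and the interval [x, y] on a sequence covers residues
x … y−1 (0-based), so [x, x] is empty.  A window [(i₁,j₁), (i₂,j₂)]
projects to [i₁, i₂] on *A* and [j₁, j₂] on *B*.  For S = "AB" and
T = "BC" aligned as "AB-"/"-BC", the window of the first gap,
[(0,0), (1,0)], projects to [0, 1] on S and to the empty interval [0, 0]
on T: residue T[0] is *not* part of the window even though the B characters
line up in the rendered alignment.  BED export uses the same numerals as
0-based half-open residue intervals.

## Parameters

* **α** (`alpha`, default 0.75): safety proportion threshold, a rational
  in (0.5, 1].  1 demands presence in *every* path; 0.51 is the loosest
  value with a guaranteed spanning path.  Comparisons are inclusive
  (p ≥ α).
* **Δ** (`delta`, default 8): score slack defining the suboptimal space,
  an integer on the scale of the substitution scores (BLOSUM62 entries
  range from −4 to 11).  Δ = 0 restricts to co-optimal alignments; larger
  Δ widens the space and shortens windows.  `Inf` is accepted as a
  documented special case meaning the whole graph.
* **Gap scores** (`gap_open` p = −11, `gap_extend` g = −1): the customary
  BLOSUM62 pairing.  These are package defaults chosen by convention, and
  both are configurable.
* **Substitution matrix**: bundled BLOSUM62 in the standard NCBI 24-symbol
  text layout; any matrix in that format can be supplied.  Residues
  outside the matrix alphabet score `wildcard` (default −4, the BLOSUM62
  `*` penalty) against everything; setting `wildcard = NULL` turns unknown
  residues into errors.
* **`merge`** (window-merge mode, `-m/--windowmerge` on the command line):
  joins windows that intersect or are adjacent on the representative
  projection.  The merged window spans the union and its proportion is
  recomputed exactly over the spanned subpath — it may fall below α, which
  is why merged rows carry a `merged` flag.  Merging is a presentation
  convenience, not a change of definition.

## Determinism and tie-breaking

Wherever a choice among equivalent edges arises (the default spanning path
when few edges are safe, anchor stitching, the optimal-alignment traceback
used for `pairwise_identity()`), the package applies one fixed preference
order: the aligned pair first, then the gap consuming *A*, then the gap
consuming *B*; inside a gap, closing before extending.  End-to-end runs on
identical inputs are byte-identical.

## Degenerate inputs and numerics

Empty sequences are legal: an empty pair has OPT = 0 and no windows; a
pair with one empty sequence has the single forced gap path.  Terminal
gaps are penalized like internal gaps (global alignment; there is no
free-end-gap mode).  Non-integer or negative Δ is rejected.  α arriving as
a decimal is converted to an exact small fraction from its printed
representation ("0.51" → 51/100); a string "num/den" is accepted for exact
control.  The `gap_model = "linear"` option collapses the gap states
(every gap residue is an open-close step, gap(ℓ) = ℓ·g); in that model
s–t paths are in bijection with monotone lattice paths, which is what the
Delannoy-number identities in the test-suite check.  In the affine model
the graph additionally contains close-then-reopen gap structures, so its
full-graph path count intentionally exceeds the Delannoy number — those
paths are real s–t paths and are counted, with their extra open penalties,
throughout.

## What the synthetic generator emulates

`generate_cluster()` produces a representative drawn uniformly over the 20
standard residues and members derived by per-residue substitutions
(probability `sub_rate`, default 0.15), and indels (per-position
probability `indel_rate` 0.03, uniform length 1–5).  The defaults describe
a moderately diverged cluster of four members around a 120-residue
representative — the size regime in which window structure is interesting
but desk-scale exact counting stays fast.  The generator is seeded and
restores the caller's RNG state; the "conserved" mask it returns (positions
never substituted or deleted) is a stand-in stable label for metric tests,
*not* a secondary-structure annotation.  The generator deliberately omits
realistic evolutionary features — no substitution-rate matrices over time,
no position heterogeneity, no empirical indel length distribution, no
compositional bias.  Passing tests on synthetic clusters therefore
demonstrate algorithmic correctness (against exhaustive oracles) and
pipeline behavior, not biological performance on real protein families;
for the latter, windows should be benchmarked against real structure
annotations via `safety_report()`.

## Benchmarking metrics

Given per-residue secondary-structure types (the seven Stride classes),
residues of type Coil, Strand or Turn are labeled not stable and the rest
stable.  A residue is TP when safe and stable, FN when stable but not
safe, FP when safe but not stable; stable-structure retention (recall) is
TP/(TP+FN), stable-structure overlap (precision) TP/(TP+FP), and F1 their
harmonic mean.  Undefined ratios are reported as `NA`, never 0.  Residues
with no annotation record are excluded from the confusion counts but do
count in the safety-coverage denominator, keeping coverage a pure sequence
fraction.  Pairwise identity for binning is computed on the package's own
deterministic optimal traceback (identical aligned pairs / alignment
columns), so reports are reproducible without any external clustering
tool.

## Verification strategy and problem sizes

Every engine decision is checked against brute force on small instances:
an oracle enumerates all alignments (and all gap-split path structures),
takes the Δ-suboptimal set, derives the induced subgraph, enumerates its
s–t paths explicitly, computes every contiguous subpath's containment
proportion by counting, and keeps the maximal α-safe ones.  The test suite
runs 200+ seeded random instances with sequence lengths 2–6, Δ ∈ 0..10 and
α ∈ {0.51, 0.75, 1}, requiring exact agreement of window coordinates and
exact rational agreement of proportions; bridge-finding (for α = 1, Δ = 0
the safe edges are exactly the bridges of the undirected optimal subgraph)
is cross-checked against an independent graph library.  These sizes keep
the exhaustive oracles exact and the default test run fast; the engine
itself runs comfortably on realistic protein lengths (hundreds of
residues).

## Known limitations

* Proportions are over s–t paths of the Δ-subgraph, not over true
  Δ-suboptimal alignments (see above); exact only in the subgraph sense.
* α ≤ 0.5 is not supported.
* Global alignment only — no local (Smith–Waterman) or free-end-gap mode,
  and no banded heuristics: time and memory are Θ(n·m) per pair with
  big-integer factors on top.
* The Δ-sweep idea of tracking windows that persist across increasing Δ is
  out of scope for this version.
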