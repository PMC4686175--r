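---
title: "Measuring cell tracking accuracy by matching acyclic oriented graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cell tracking accuracy by matching acyclic oriented graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aogm)
```

## The problem

Time-lapse microscopy experiments routinely require following every cell (or
nucleus) through hundreds of frames while cells migrate, divide, die, and
enter or leave the field of view.  A tracking algorithm's output can be
represented as an *acyclic oriented graph*: each vertex is a **marker** — the
set of pixels carrying one object's label in one frame — and each edge links
a marker to its successor(s) in time.  Edges carry one of two semantics: a
**track link** joins consecutive markers of the same track, and a **parent
link** joins the terminal marker of a track to the initial marker of a
descendant track (a daughter after division, or the same object reappearing
after a temporal gap).  A lineage forest in the graph-theoretic sense.

Given a ground-truth reference graph $G_R$ and a computed graph $G_C$, this
package scores a tracking algorithm by how difficult it is to *transform*
$G_C$ into $G_R$, counting the minimum number of elementary graph operations
and weighting each by the effort its correction costs.

## The model

**Detection test.** A reference marker $R$ is assigned to a computed marker
$C$ of the same frame iff $|R \cap C| > 0.5\,|R|$ — a *strict* pixel
majority.  Because computed markers within one frame are disjoint, at most
one computed marker can hold a strict majority of any reference marker, so
the assignment is unique and needs no combinatorial optimisation.  We keep
the inequality strict: an exactly-half overlap fails, which matters for
rasterized fixtures that can hit the boundary case.  A one-pixel expert dot
inside a large computed region is covered completely and matches — the
intended behaviour for point-annotated ground truth.

**Vertex classification.** Reference vertices split into true positives
(assigned somewhere) and false negatives ($FN$).  Computed vertices split
into true positives (exactly one reference marker assigned), false positives
($FP$, none assigned) and *non-split* vertices ($\ge 2$ assigned — typically
an undetected division leaving daughters clustered in one marker).  A
non-split vertex holding $m$ reference markers needs $m - 1$ split
operations, so the total split count is
$NS = TP - |\{C : \text{some } R \sqsubset C\}|$.

**Edge classification.** Edge errors are evaluated on the *induced subgraph*
of the computed graph restricted to its uniquely matched vertices: edges
touching false-positive or non-split vertices disappear anyway when those
vertices are deleted or split, so they never double-count.  On that subgraph,

* a **redundant** edge ($ED$) is an induced edge whose reference endpoint
  pair is not a reference edge;
* a **missing** edge ($EA$) is a reference edge with no matching induced
  edge (matching requires both endpoint detection tests, hence identical
  frame indices at both ends);
* a **wrong-semantics** edge ($EC$) is a matching pair where a track link
  stands in for a parent link or vice versa.

**Aggregation.** The measure is
$$\mathrm{AOGM} = w_{NS} NS + w_{FN} FN + w_{FP} FP
  + w_{ED} ED + w_{EA} EA + w_{EC} EC ,$$
with non-negative weights and at least one positive.  It is zero exactly
when every positively weighted error vanishes.  Two variants answer narrower
questions: *AOGM-D* (only vertex weights positive) scores detection skill,
*AOGM-A* (only edge weights positive) scores association skill, and by
linearity the full value is their sum.

**Minimality.** A non-split vertex with $m$ assigned reference markers could
also be fixed by deleting it and adding $m$ vertices.  The reported value is
the *minimum* transformation cost whenever
$w_{NS}(m^\star - 1) \le w_{FP} + w_{FN} m^\star$, where $m^\star$ is the
largest fiber size in the comparison; the input-independent weakened form is
$w_{NS} \le w_{FN}$.  `check_minimality()` reports both flags, and the suite
verifies by exhaustive enumeration over $m \le m^\star$ that the split
strategy is never costlier when the condition holds.

## Parameters that matter

* **Weights** (`aogm_weights()`): default `(5, 10, 1, 1, 1.5, 1)` for
  `(ns, fn, fp, ed, ea, ec)` — the reference configuration of the first
  Cell Tracking Challenge, reflecting the relative manual effort of
  correcting each error in an editing tool.  It satisfies the minimality
  condition for every $m^\star$.  Weights are unitless penalties; only their
  ratios affect rankings.
* **Variant**: `full`, `detection`, or `association`, as above.
* **Sector maps** (`sector_map()`): default domain $(0,10)\times(0,20)$ for
  the `(ns, fn)` pair — zero to double each reference weight, centred on the
  reference configuration — with a 201-point grid per axis.

## Worked example

```{r}
ex <- worked_example()
cmp <- compare_tracking(ex$reference, ex$computed)
cmp
aogm(cmp)
```

The shipped pair (25 reference markers in 8 tracks over 5 frames against 18
computed markers in 9 tracks) packs every error type into one scene: three
frames of an undetected division plus two fused track pairs give the 5
non-split sites, a track is missed entirely for three frames, two divisions
are faked as plain track continuations (wrong semantics), a track end is
stitched onto an unrelated newborn track (redundant edge), and a spurious
track adds three false positives.  The resulting census — `NS=5, FN=5, FP=3,
ED=1, EA=16, EC=2` — aggregates to $25+50+3+1+24+2 = 105$ under the default
weights.

## Weight sensitivity

Rankings of several algorithms under one weight configuration are compiled
with `rank_algorithms()` (ascending measure value; exact ties are flagged,
never broken silently).  `sector_map()` evaluates the ranking over a 2-D
grid of weight pairs and groups equal-ranking cells into sectors.  Because
the measure is linear in the weights, true sectors are polygons; we sample
them on a grid rather than solving the boundary inequality systems exactly —
the polygon boundaries are of interest only through their areas, and grid
refinement changes a sector's area at most by its perimeter cells (a
property the suite checks).  Cells where two algorithms tie exactly go into
a `"tie"` pseudo-sector.  `transpositions()` reports the Kendall
discordant-pair distance of each sector's ranking from the ranking at the
reference point (domain centre by default).

## The synthetic generator

`generate_reference()` emulates what a tracking benchmark must represent —
migration (an integer random walk), division (mother track ends, two
daughters start with parent links), disappearance (track ends), and
appearance (a new parentless track) — while guaranteeing structural
validity: markers are axis-aligned squares kept disjoint by a minimum
Chebyshev separation of centres, spans are gap-free, and parents terminate
strictly before children start.  One daughter inherits the mother's position
and the other buds off at a fixed offset, which stays feasible next to the
image border.  Reappearance after a temporal gap is *not* generated (the
model supports it; the generator keeps event semantics unambiguous).

Defaults describe a desk-scale fluorescence-nuclei-like series: 20 frames of
$128 \times 128$ pixels, 8 initial cells of half-width 2, division 2 %,
disappearance 1 % per cell and frame, one appearance attempt at 2 % per
frame, steps up to 3 px per axis.  The test-suite instances use 8 frames,
$64 \times 64$ px and 5 cells with slightly raised event rates so every
event type appears often at small cost; all property loops state those sizes
in the test code.

What the generator does **not** emulate: irregular marker shapes, touching
cells, intensity noise, segmentation jitter, or anisotropic 3-D voxels.
Passing the synthetic suites therefore certifies the *counting machinery* on
exactly-known topologies, not robustness to real segmentation noise — on
real data the detection test sees arbitrary pixel sets, which the measure
handles but the generator never produces.

`inject_errors()` corrupts a reference with a script of spatio-temporally
disjoint edits, each mapping one-to-one onto an error type with an exactly
predictable count delta (`?edit_script_edits` lists all six).  Disjointness
of edit sites is what makes the deltas additive, and is enforced.  The
central property — 500 seeded (reference, script) pairs recover the
predicted counts *exactly* — ties the implementation to the error
definitions through an independent route: the deltas are derived from the
definitions on the edit's local neighbourhood, never from running the
comparison code.  A separate brute-force all-pairs matcher cross-checks the
assignment stage on small instances.

## Numerical and design choices

* Counts are integers and the default weights are dyadic rationals, so
  double-precision aggregation is exact; no rational layer is needed.
* The exactly-half overlap fails the detection test (strict majority).
* Edge matching requires identical frame indices at both endpoints; this
  falls out of the endpoint detection tests and is asserted structurally.
* $m^\star$ of a comparison without non-split vertices is defined as 1, so
  the minimality condition is trivially satisfiable.
* Markers need not be connected; a label's full per-frame support is one
  marker.
* Temporal evolution (`temporal_evolution()`) recomputes the comparison per
  frame prefix rather than updating incrementally — linear extra cost,
  unambiguous semantics.  The series is non-decreasing: restricting to a
  prefix never un-counts an error.
* Track labels are positive integers; parent `0` in the on-disk dialects
  encodes "no parent", `NA` in memory.  Masks are written as 16-bit unsigned
  TIFF, so labels above 65535 are rejected at write time.
* A parent may have more than two children (abnormal division) and a parent
  link may bridge an arbitrary temporal gap ($t_1 < t_2$ suffices).

## Limitations

* Segmentation accuracy (contour agreement) is out of scope; the measure
  only requires majority coverage.
* No normalised 0–1 score is provided — the measure is an unbounded cost.
* Published benchmark tables that depend on the original challenge
  submissions cannot be recomputed here; printed measure values can still be
  fed to `rank_algorithms()` directly, and the ranking/sector machinery is
  exercised on synthetic count sets instead.
* The sector maps are grid approximations of polygonal sectors; areas are
  accurate to the perimeter-cell fraction of the grid.
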