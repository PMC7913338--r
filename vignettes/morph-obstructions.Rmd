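---
title: "Steric and topological obstructions to protein structure superposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Steric and topological obstructions to protein structure superposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphcheck)
```

## The problem

Structural alignment scores — RMSD, GDT-TS, the TM-score — are functions of
the distances that aligned residues travel between two superimposed backbone
conformations.  They measure proximity in the space of *immersed* curves:
nothing in them asks whether the straight-line interpolation between the two
conformations can actually be performed by a physical chain.  Two backbones
can differ only by an over/under exchange at one crossing and still score
like near-identical structures, even though any morph connecting them must
pass the chain through itself.

`morphcheck` analyzes the linear morph
$P(t, a) = (1-t)\,P^0_a + t\,P^1_a$, $t \in [0,1]$, between two aligned,
superimposed piecewise-linear backbone curves and answers three questions:

1. **How much steric overlap** does the interpolation create, measured
   against minimum CA–CA distances observed in native structures?
2. **Which transversal self-intersections** occur, i.e. at which times and
   backbone positions does one segment pass through another?
3. **Which of those self-intersections are removable** by local
   modifications of the morph — 3-dimensional analogues of Reidemeister
   moves of types 1 and 2, or a contraction of a chain terminus — and which
   remain as *essential* obstructions?

A worked demonstration:

```{r example}
pair <- make_crossing_change_pair(100)
d <- sqrt(rowSums((pair$chain1$points - pair$chain0$points)^2))
alignment_scores(d)

ali <- alignment_record(cbind(1:100, 1:100), n0 = 100, n1 = 100)
analyze_pair(pair$chain0, pair$chain1, ali, morph_config(max_length = 4))
```

Excellent scores, one essential self-intersection: the morph changes the
threading of the chain.

## The model, step by step

### Overlap

For vertices $i < j$ the squared inter-point distance
$d^2_{ij}(t)$ is quadratic in $t$; its unconstrained minimizer is
$t^* = (a^2 - ab\cos\theta)/(a^2 + b^2 - 2ab\cos\theta)$ with
$a = \lVert p_0^{ij}\rVert$, $b = \lVert p_1^{ij}\rVert$, and the minimum
over $[0,1]$ is taken at its clamp (constant distance in the degenerate
branch).  The pair's overlap is
$\max(d_{\min}(|i-j|) - d^{\text{interp}}_{ij},\, 0)$, penalized linearly,
and MeanOverlap is the sum over pairs divided by the chain length.  The
$d_{\min}$ table for CA curves is 2.8, 4.5, 3.86, 3.47, 3.52, 3.48, 3.6 Å
for separations 1–7 and 3.7 Å beyond; the value at separation 1 is kept
deliberately small so helix compression does not dominate.  The smooth
representation uses 1.0, 2.1, 3.0, 3.4, 3.6 Å (separations 1–5) and 3.7 Å
beyond.

### Self-intersections

Two moving non-adjacent segments are coplanar exactly at the real roots of
a cubic, the determinant of the frame spanned by the two segment vectors
and their offset.  At each isolated root in $[0,1]$ a planar
2-unknown linear system decides whether the coplanar segments actually
cross; the crossing-sign change is the sign of the cubic's derivative at
the root.  Roots whose derivative magnitude falls below $10^{-8}$ of the
coefficient scale are tangential contacts, not transversal intersections;
they are discarded and counted in the diagnostics.  Root finding uses the
closed-form solution (`polyroot`) followed by a few Newton polish steps,
with tolerance $10^{-9}$ on the normalized polynomial; roots within
tolerance of $t = 0$ or $1$ are kept but flagged, since transversality at
the interval ends is genuinely ambiguous.  A pre-computed overlap filter
skips segment pairs whose four neighbor spacings stay below 4 Å (3.5 Å
smooth) with a four-term overlap sum below 2.6 Å (2.1 Å smooth); segment
lengths are convex in $t$, so checking the two end structures bounds all
intermediate times.

### Removability and prices

An intersection $(a_k, b_k, \mathrm{sign}_k, t^*_k)$ is **Ω₁-removable**
when its span $b_k - a_k$ is at most the user's MaxLength and the triangle
fan spanned from the loop boundary at time $t^*_k$ to the loop centroid is
disjoint from the rest of that time slice.  Its price $\mathscr{P}1$ is
twice the sum of loop-point distances to the rotation axis through the
intersection point and the centroid.  A pair of opposite-sign intersections
is **Ω₂-removable** when the combined span is within MaxLength, the disk
spanned at the average time is free, and the tracks swept by the two
intersection points between their times stay clear of the moving curve; the
price $\mathscr{P}2$ is twice the sum of loop-point distances to the line
joining the two intersection points.  Disk-freeness sorts candidate
segments by distance from the loop centroid and stops as soon as the
triangle inequality excludes the remainder.  The Ω₂ tracks are sampled at
64 uniform times and required to keep more than $10^{-6}$ Å clearance —
the sweep is a smooth surface and the discretization is only used as a
conservative proximity probe.

### The essential set

With $\varepsilon$ equal to one over twice the total price of all feasible
moves, each vertex gets weight $\varepsilon\mathscr{P}1$ (Ω₁-removable) or
1, and each feasible Ω₂ edge weight
$w(e) = w_v(v_i) + w_v(v_j) - \varepsilon\mathscr{P}2$.  For every matching
$E'$,
$N(E') + \varepsilon\mathscr{P}(E') = K + \varepsilon\mathscr{P}1_{all}
- \sum_{e \in E'} w(e)$,
so one maximum-weight matching minimizes the number of remaining
self-intersections and, among such solutions, the total price.  The package
solves this exactly with a memoized branch-and-bound over the edge list —
graphs here have one vertex per morph self-intersection, so exhaustive
optimality is cheap — and also offers the faster greedy scan by increasing
backbone length, which can strand vertices an optimal matching would pair.
Ties among equal-weight optima are broken toward the edge set earliest in
the (backbone length, t*) order; tie-breaking can change which
intersections are *called* essential but never how many, and the count is
the quantity to report.

### End-contractions

An essential intersection near a terminus can be avoided by retracting the
terminus: all points upstream of the obstruction parameter move to it,
straight-line when the connecting triangle is clear of the downstream
curve, otherwise via an obstruction point chosen inside the triangle
(barycentric grid of 15×15 candidates plus points offset 0.5 Å from each
blocking crossing) minimizing the two-leg path.  The search is greedy and
one-pass: an accepted path tail is reused by all further upstream points.
The cost sums the travel in both end structures plus $m$ times the
displacement of the contraction target under the morph.  Minimizing the
N/C contraction pair subject to covering all essentials needs only the
$n+1$ candidate pairs $a = a_j$, $b = \min(b_{j+1}, \dots, b_n, L)$.  A
linear-ramp estimate (distance grows to 25 Å over 17 residues, constant
beyond) replaces the exact construction when speed matters.

### Morph length

When a self-avoiding morph exists its length is estimated as the $L^1$
morph length (summed vertex displacements) plus the move prices, plus a
chain-thickness penalty $\pi d/2$ per residue interval affected
($d = 3.7$ Å, the minimal overlap-free distance: each point must travel
half a circle of radius $d/2$ to exchange over- for under-sliding), plus
any end-contraction cost.  Optional weighted terms add the mean overlap
and the net torsional effect (the absolute signed sum of Ω₁-removed
crossing signs; Ω₂ pairs cancel); both weights default to 0 so the default
total matches the primary definition.

### Alignments with gaps

A TM-align-style alignment (":" strong, "." weak — treated as aligned —
and "-" gaps) is converted to two equal-length parameter lists: between
consecutive aligned pairs spanning $g_0$ and $g_1$ intervals,
$\max(g_0, g_1)$ uniform steps are inserted so both curves arrive
simultaneously, fractional positions being evaluated on the segments.  On
the canonical 12-vs-10-residue example this yields re-parameterization
$[3, 4, 5, 6, 7, 7.75, 8.5, 9.25, 10, 11]$ against
$[1, 2, 2.5, 3, 4, 5, 6, 7, 8, 9]$ with IsAligned
$[1,1,0,1,1,0,0,0,1,1]$:

```{r reparam}
build_reparam(make_worked_alignment())
```

IsAligned interpolates linearly on segments; an intersection is
aligned–aligned when $\mathrm{IsAligned}(a_k) + \mathrm{IsAligned}(b_k)
\ge 1.5$, gap–gap below 0.5.  $d_{\min}$ at the fractional separations of a
re-parameterized morph interpolates the table — 3.51 Å at separation 4.80.
Where the two chains disagree on a pair's separation (inside gaps), the
package takes the weaker of the two interpolated constraints, which reduces
to the plain table on gapless stretches.  The aligned window fraction (AWF)
is the shorter aligned window over the shorter chain length.

### Smoothening

The smooth representation replaces each interior point by the convex
combination with weights $1, a, b, a, 1$, $a = 2.4$, $b = 2.1$ (normalized
by 8.9), keeping two points at each end.  It straightens helices and
strands the way cartoon renderings do and roughly halves the number of
morph self-intersections; the overlap filter is correspondingly less
effective, which is why its thresholds differ.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `max_length` | 10 residues | largest backbone span one Ω move may rearrange; 0 makes every intersection essential |
| `representation` | `"alpha"` | raw CA trace or 5-point smoothened curve |
| `allow_end_contractions` | `FALSE` | try terminus retractions for remaining essentials |
| `end_contraction_limit` | `max_length / 2` | residues a terminus retraction may involve |
| `solver` | `"optimal"` | exact matching, or `"greedy"` by increasing length |
| `torsion_penalty_weight`, `overlap_weight` | 0 | optional morph-length terms |
| `use_cost_estimates` | `FALSE` | linear-ramp contraction costs instead of exact paths |

MaxLength is the knob that encodes the user's notion of "the same fold":
larger values permit larger rearrangements before an intersection is called
essential, and the essential count is non-increasing in it.

## What the synthetic fixtures emulate — and what they do not

The generators produce the study conditions deterministically, with no
structure downloads:

* `make_crossing_change_pair(n)` embeds the symmetric crossing exchange
  (over-strand heights 0, 0, 1.25, 2.5, 2.5, 1.25, 0, 0 Å against the
  negated under-strand) in a clash-free serpentine whose return route stays
  more than 12 Å from the crossing, so the single morph event is the swap:
  4 residues travel 5 Å, 4 travel 2.5 Å, RMSD $< 12/\sqrt{n}$ Å.  The
  scaffold needs about 65 residues for the return route, so the generator
  requires $n \ge 70$.  Static scaffold points carry a fixed ±0.35 Å
  out-of-plane wiggle so no segment pair is exactly coplanar for all $t$ —
  without it the $t = 1/2$ slice would be entirely planar and every
  determinant cubic degenerate.
* `make_loop_fixtures()` builds a handedness-flipping loop (Ω₁-feasible),
  the same loop threaded by a strand through its spanning disk
  (Ω₁-blocked), and a hairpin slide producing two opposite-sign
  intersections at slightly different times (Ω₂-feasible; the height
  asymmetry separates the times so the swept-track check is exercised).

These fixtures have exact CA spacing, isolated events and clash-free
endpoints.  Real structures have correlated local geometry, many
simultaneous near-events, and alignment gaps everywhere; passing tests on
the fixtures validates the algorithms and formulas, not distributional
claims about protein fold space.  Large-scale survey statistics are out of
scope and covered only as property-level analogues (e.g. monotonicity of
the essential count in MaxLength).

## Numerical choices and degenerate inputs

* Cubic roots: closed form plus Newton polish; tolerance $10^{-9}$;
  near-identically-zero cubics (segment pairs coplanar at all times) are
  skipped and counted — a transversal crossing cannot hide there.
* Planar containment: least squares on the 3×2 system with residual check;
  $10^{-9}$ slack on $[0,1]$ containment.
* Segment–triangle tests treat touching within tolerance as intersection
  (conservative for disk-freeness) and handle the coplanar case by an
  explicit 2-D test; zero-area triangles are skipped.
* The downstream curve in end-contractions starts 0.05 parameter units past
  the contraction target so paths that legitimately end on the target are
  not flagged for touching it.
* Chains must have ≥ 3 distinct consecutive points; smoothening needs ≥ 5;
  TM-scores require $n > 15$ (otherwise $d_0 \le 0$ and `tm` is `NA` while
  RMSD and GDT-TS are still returned).
* Exact matching is exponential in the worst case but memoized; morphs in
  the intended regime have tens of intersections, and the greedy solver is
  the documented fallback for pathological inputs.

## Open design points resolved here

* **Gap-filling with unequal block counts.** The uniform-step rule (insert
  $\max(g_0, g_1)$ steps, advance each curve linearly) is used for every
  block; it reproduces the printed worked example exactly and keeps both
  parameter lists strictly increasing.
* **Which chain's separation for $d_{\min}$ in gaps.** The weaker of the
  two chains' interpolated constraints, since a pair legitimately as close
  as the smaller table value in one chain cannot be penalized at the
  larger one.
* **Neighbor-spacing side condition of the overlap filter.** Required in
  both structures (convexity in $t$ makes the endpoint check sufficient),
  which is the conservative reading.
* **Ω₂ track handling.** The swept tracks are tested separately against
  the moving remainder rather than folded into the disk triangulation.
* **Global alignment placements.** The one-inner-gap search enumerates
  start offset, gap position, gap length and end offset exhaustively —
  cost is one Kabsch fit per placement.
* **Candidate-set optimality of end-contractions.** The $n+1$-case rule is
  exact when the contraction cost is non-decreasing in the contracted
  length, which holds when the path cost dominates; the displacement term
  $m \cdot \lVert P_{a}(1) - P_{a}(0)\rVert$ can fluctuate on artificial
  jagged displacement fields, where the rule is a (documented) heuristic.

## Problem sizes used in the test suite

The suite regenerates everything programmatically: crossing pairs at
$n \in \{70, 80, 100, 144\}$, 200 random 12-vertex morphs against a
dense-time-sampling detector oracle, 1000 random vertex pairs against
grid+Brent distance minimization, 500 random disk/curve instances against
the unsorted all-pairs test, 50 random move graphs against exhaustive
matching enumeration, and dense (a, b) scans of the end-contraction
optimizer on the fixtures.  These sizes keep the whole suite in the
tens-of-seconds range on one core while still exercising every branch;
all random cases run under fixed seeds.

## Known limitations

* Ω₃-type moves and multi-pass disk deformations around blockers are not
  attempted; an intersection whose removal needs them is reported
  essential.  Essentiality is therefore a geometric statement — every
  self-avoiding morph must leave a MaxLength-sized neighborhood of the
  linear interpolation — not a topological invariant.
* The morph length is an upper-bound estimate of a nearby self-avoiding
  morph, not a geodesic; end-contraction paths are greedy and one-pass.
* PDB input is CA-only and single-model-at-a-time; mmCIF is not read.
* TM-align is consumed, not re-implemented: alignments come from its text
  output or from the package's own global RMSD search.
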