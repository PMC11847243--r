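---
title: "The symmetric division Szeged index: models, bounds and the octane study"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The symmetric division Szeged index: models, bounds and the octane study}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(szind)
```

## The model

For a simple connected graph $G$ with $n$ vertices and $m$ edges, each
edge $e = uv$ partitions the vertex set into three classes: vertices
strictly closer to $u$, vertices strictly closer to $v$, and
equidistant vertices.  Writing $n_u$, $n_v$, $n_0$ for the class sizes
($n_u + n_v + n_0 = n$, and $n_u, n_v \ge 1$ because each endpoint
counts itself), the symmetric division Szeged index is

$$SDZ(G) \;=\; \sum_{uv \in E(G)} \left( \frac{n_u}{n_v} + \frac{n_v}{n_u} \right).$$

This is the cut-count analogue of the symmetric division degree index
$SDD(G) = \sum (d(u)^2 + d(v)^2)/(d(u)d(v))$: both arise from the
generalized form $GSDD_f(G) = \sum (f(u)/f(v) + f(v)/f(u))$, with
$f$ the degree for SDD and the per-edge closer-vertex count for SDZ.
Because $x + 1/x \ge 2$, every edge contributes at least 2, giving the
defining inequality $SDZ(G) \ge 2m$ with equality exactly on
distance-balanced graphs ($n_u = n_v$ on every edge).  In chemical
terms SDZ is a branching-sensitive descriptor: on molecular skeleton
trees, pendant edges contribute the extreme split $1/(n-1) + (n-1)$,
so branched skeletons score systematically higher than path-like ones.

Equidistant vertices are excluded from both counts — no tie-break ever
assigns them.  Cut counts and distance-balance detection are exact
integer computations; the index sums are double precision, accumulated
in sorted $(\min, \max)$ edge order so results are bit-for-bit
reproducible on a given platform.  On bipartite graphs $n_0 = 0$ on
every edge, which yields the exact identity
$SDZ(G) = n^2 \, RSz(G) - 2m$ used as a cross-check in the tests.

## Assumptions and input contract

All index operations require a connected graph (disconnected input is
representable and parseable, but index functions refuse it with an
error); distances are unweighted BFS hop counts.  Graphs are simple:
the edge-list parser collapses duplicate edges and rejects self-loops.
Vertices are `1..n`; files with 0-based or arbitrary integer labels
are accepted because labels are remapped in first-appearance order.

## The bound catalog as executable checks

Each named result is a function of the graph returning a structured
report (both side values, an applicability verdict, equality flags)
rather than a bare boolean, so hypothesis violations are visible and
equality characterizations are audited in both directions.  Two
numerical conventions apply throughout: integer-valued comparisons are
exact, floating comparisons use an absolute tolerance of $10^{-9}$
(index values on the enumerated graphs are of magnitude $10^0$–$10^2$,
far from the scale where $10^{-9}$ would be ambiguous).

Two of the printed source formulas required a decision:

* **Radical lower bound (`P3.1`).**  The bound is implemented as
  $SDZ(G) > \tfrac{1}{8}(\sqrt{32m+1}+1)$, which is equivalent to
  $(SDZ - \tfrac18)^2 > \tfrac{m}{2} + \tfrac{1}{64}$ — the form the
  chain of inequalities behind it actually proves (square the
  arithmetic–geometric comparison $4\,AG2^2 - 2m > SDZ$ and use
  $AG2 < SDZ$).
* **Unicyclic upper bound (`T4.3`).**  The printed closed expression
  $(n-3)\frac{n^2-2n+2}{n-1} + 2\frac{n^2-2n+4}{n-2} + 2$ disagrees
  with the per-edge values of its own derivation (at $n = 6$ it gives
  31.6, while the SDZ of the claimed extremal graph — the triangle
  with $n-3$ pendant leaves on one vertex — is 26.1).  The implemented
  bound is the derivation-consistent value
  $(n-3)\frac{n^2-2n+2}{n-1} + 2\frac{n^2-4n+5}{n-2} + 2$, which the
  exhaustive enumeration confirms is attained by, and only by, that
  extremal graph for $4 \le n \le 8$; the printed expression is kept in
  the report notes for transparency.

The triangle-count bound (`T4.4`) is stated for planar triangulations,
but its proof uses only the triangle count $t(G)$, the order and the
size; the checker therefore requires only $t(G) \ge 1$ (which also
guarantees the strict step, since a triangle provides three edges with
common neighbours) and flags every report `hypothesis_unverified`
because planarity testing is out of scope.

A related design choice: the arithmetic–geometric comparison is
implemented and tested as $AG2(G) \ge \tfrac12\sqrt{SDZ(G) + 2m}$,
strict for $m \ge 2$.  A superficially similar non-radical form
("$AG2 > (SDZ+2m)/2$") is false on every distance-balanced graph and
is a rendering artefact of flattened fractions, not a theorem.

## Enumeration

Free trees are grown by leaf attachment with isomorphism
deduplication at every size; unicyclic graphs are spanning trees plus
one non-edge, deduplicated the same way; connected graphs on at most 6
vertices come from exhausting edge subsets of $K_n$.  Deduplication
and the deterministic output order both use BLISS canonical forms
(`igraph::canonical_permutation`) serialized to a sorted edge-list
string — a single, well-tested canonical-form mechanism instead of a
hand-rolled AHU tree encoding; the contract (one representative per
class, stable order) is the same.  Practical caps: trees $n \le 12$,
unicyclic $n \le 9$, connected $n \le 6$.  The class counts are
verified against independent brute-force oracles in the test suite
(all Prüfer sequences for trees up to $n = 7$; all fixed-size edge
subsets for unicyclic graphs up to $n = 6$; the larger frozen counts —
23 trees on 8 vertices, 33 unicyclic classes on 7 — were produced by
the same oracles run at full size).

## Graph products

The join, corona, Cartesian and lexicographic products are constructed
directly from the documented vertex-numbering contract (pair $(i,j)
\mapsto (i-1)n_2 + j$ for the last two; block layouts for join and
corona).  Bound verification always computes the SDZ of the
constructed product graph through the ordinary cut-count path — never
through the case decompositions used to prove the bounds — so the
product theorems are tested against an independent computation.  The
Cartesian identity $SDZ(G_1 \times G_2) = n_2 SDZ(G_1) + n_1 SDZ(G_2)$
is exact; the join, corona and lexicographic results are lower bounds
whose stated equality conditions (regularity with matching $n - k$;
complete inner factor; regular inner factor with distance-balanced
outer factor) are checked whenever they hold.  For the corona the
equality condition is treated as sufficient only.  `SDD` of an
edgeless factor is 0 (empty sum), which admits the pendant corona
$G \circ K_1$.

## The Hosoya root indices M1 and M2

For each vertex $v$, the partial Hosoya polynomial
$H_v(x) = \sum_{k \ge 1} c_k x^k$ encodes the distance distribution
from $v$.  All complex roots are taken with multiplicity, including
the zero root contributed by the missing constant term.  With
$\mu(v) = \sum |z|$ over the roots of $H_v$, the package computes

$$M_1 = \sum_v \mu(v), \qquad M_2 = \sum_v \sqrt{\mu(v)}.$$

The verbal definitions of these indices in the literature leave the
placement of the square root ambiguous (per root, or per vertex).  The
per-vertex convention above is the one that reproduces the published
octane reference columns: over all 18 isomers the computed $M_1$ and
$M_2$ agree with the packaged table within 0.01 (maximum deviation
0.005), which the test suite asserts.  The entropy-like companion
index sometimes tabulated alongside them has no computable definition
and ships only as fixture data.

## The octane study

The 18 constitutional isomers of octane have carbon skeletons that are
exactly the trees on 8 vertices with maximum degree at most 4, so the
dataset is *regenerated*, not stored: `enumerate_trees(8, 4)` yields
the skeletons, SDZ/SDD/SDE are computed at full precision, and each
skeleton is paired with one row of the packaged printed property table
by nearest (SDZ, SDD, SDE) triple.  The pairing must be a perfect
bijection with every deviation at most 0.01 — the printed table mixes
rounding and truncation (27.4857 appears as 27.48 but 44.8571 as
44.86), which 0.01 absorbs — and the fixture loader asserts that no
two printed rows collide within twice that tolerance, so the matching
is self-validating.  Row order in the printed table is never assumed
to correspond to any isomer ordering; IUPAC names are attached by
isomorphism against built-in skeleton SMILES and serve as labels only.
A column-sum checksum guards the fixture against accidental edits.

Acentric factor and entropy are experimental properties and ship as
printed fixture columns.  Pearson correlations use the standard sample
formula at full precision; the 2-dp display rounds half-up, matching
how the reference table is printed.  Correlations of computed indices
(SDZ–SDD 0.88, SDZ–SDE 0.85, SDD–SDE 0.68) use the full-precision
regenerated columns; correlations against the experimental properties
use the printed index column so that the comparison is with the table
as published.

The restricted SMILES parser accepts only the alphabet `C ( )` —
acyclic carbon skeletons with implicit hydrogens.  Rings, heteroatoms,
charges and bond orders are rejected by design; general SMILES parsing
is a non-goal.

## Problem sizes and test design

The verification suites run at sizes chosen to be exhaustive where
exhaustion is meaningful and cheap: every connected graph on at most 6
vertices (141 isomorphism classes on 2–6 vertices) for the bound
catalog, every tree up to $n = 9$ and every unicyclic class up to
$n = 8$ for the extremal orderings, 200 seeded random factor pairs
with $n_i \le 8$ for the Cartesian identity, and seeded
Erdős–Rényi connected graphs up to $n = 40$ as a spot check beyond
the exhaustive range.  The BFS cut-count path is cross-checked against
an independent Floyd–Warshall implementation at $10^{-12}$.

What the synthetic graphs do *not* emulate: weighted bonds,
heteroatoms, stereochemistry, or any property noise — the generators
produce exact combinatorial objects, so passing tests certify the
combinatorics and arithmetic, not chemical transferability beyond the
octane set.  Extending the QSPR table to nonane and beyond would need
new experimental property fixtures; the enumeration already supports
the larger skeleton sets.

## Known limitations

* Index computation is $O(nm)$ per graph via full BFS distance
  matrices — fine for molecular graphs and the enumeration caps, not
  intended for large networks.
* Isomorphism-based deduplication relies on igraph's BLISS backend;
  the documented caps keep enumeration under a minute.
* The equality direction "equality $\Rightarrow$ stated condition" for
  the join and lexicographic bounds is tested on the enumerated
  matrix; a counterexample would be logged as a source discrepancy
  rather than a build failure, but none has appeared.
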