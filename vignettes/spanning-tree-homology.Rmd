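---
title: "Computing persistent homology by all-order spanning trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing persistent homology by all-order spanning trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homtree)
```

## The simplicial-network model

A *simplicial network* is the collection of all simplices of all orders of
a simplicial complex: nodes ($0$-simplices), edges, filled triangles, and
so on, closed under taking faces. `homtree` builds one from three kinds of
input:

* a conventional network (adjacency matrix or edge list), promoted to its
  *clique complex*: every $(k{+}1)$-clique becomes a $k$-simplex
  (`build_clique_complex()`);
* a point cloud, promoted to a Vietoris–Rips complex at a distance
  threshold (`build_rips()`);
* an explicit simplex list, closed under faces with *no* clique
  completion (`build_explicit()`) — needed for triangulations such as a
  torus, where a $3$-cycle of the $1$-skeleton may deliberately remain an
  unfilled cavity.

The *boundary matrix* $B_k$ records which $(k{-}1)$-simplices are faces of
which $k$-simplices; the oriented view signs the face obtained by
deleting the vertex in position $p$ of the increasing vertex tuple with
$(-1)^p$. Writing $m_k$ for the simplex counts and $r_k$ for the GF(2)
rank of $B_k$ (with $r_0 = 0$), the Betti numbers and Euler
characteristic are

$$\beta_k = m_k - r_k - r_{k+1}, \qquad
  \chi = \sum_k (-1)^k m_k = \sum_k (-1)^k \beta_k .$$

## Spanning trees and the three simplex roles

The central computational object is the *$k$-order spanning tree*: a
maximal set of $k$-simplices whose boundary columns are independent over
GF(2). It is read off a row reduction of $B_k$ (the pivot columns), so its
size is $r_k$. Every simplex then plays exactly one of three roles:

* **tree** — a member of its order's spanning tree ($r_k$ per order);
* **paired** — a non-tree $k$-simplex matched into the $(k{+}1)$-order
  tree ($r_{k+1}$ per order);
* **critical** (cavity-generating) — the $\beta_k$ remaining simplices.
  Adding one to the complex creates a new homology class.

`classify_simplices()` performs one reduction per order. Row pivots are
scanned bottom-up (reverse lexicographic) with non-tree rows strictly
before tree rows. Because every boundary column is a cycle, and a cycle is
determined by its coordinates on non-tree simplices, each pivot provably
lands on a non-tree row; the per-order critical counts therefore equal the
Betti numbers by rank arithmetic alone.

The *pairing* additionally has to run along face incidences, or it could
not drive a discrete Morse function. The pivot-row set is kept as is — its
square submatrix against the tree columns is invertible, which is what the
homology bookkeeping needs — and the assignment of pivot rows to tree
columns is then realigned onto face incidences by augmenting paths
(bipartite matching). Invertibility over GF(2) means the submatrix
determinant is $1$, which forces at least one all-ones permutation, i.e. a
perfect face-matching always exists. Elimination pairs that already sit on
a face are kept, which is why the package reproduces the published torus
pairing verbatim; only the (rare) misaligned pairs are rematched.

## The optimal discrete Morse filtration

A function $f$ on the simplices is a discrete Morse function when every
simplex has at most one coface one order higher with a value not above
its own ($\#U \le 1$) and at most one face one order lower with a value
not below its own ($\#V \le 1$); a simplex with $\#U = \#V = 0$ is
critical. `assign_morse()` emits values in phases — component start node;
breadth-first traversal of the 1-tree with each (edge, new node) pair
sharing a value; critical edges; then per order the (paired face, tree
simplex) pairs followed by the critical simplices — so that the critical
simplices of $f$ are exactly the classification's cavity-generating
simplices. For a connected network the top value is
$n = r_1 + \beta_1 + r_2 + \beta_2 + \cdots + r_l + \beta_l$.

Higher-order pairs are emitted lexicographically through a deferral
queue: a pair is emitted only once all other faces of its upper simplex
carry values. This can permute values relative to a hand listing but
provably yields the same pairing, the same critical values, and the same
top value; a queue pass without any emission would indicate a cyclic
matching and raises an explicit error rather than producing an invalid
function. (Such complexes exist — no value assignment on the dunce hat
attains $c_k = \beta_k$ — but none of the fixtures nor the random clique
complexes exercised by the test suite trigger it.)

`build_filtration()` groups simplices by ascending value into nested
subnetworks $\emptyset \subseteq K_0 \subseteq \cdots \subseteq K_n = K$,
validating that every prefix is face-closed, and `persistence()` runs the
standard GF(2) column reduction in filtration order (ties: lower order
first, then lexicographic, so faces precede cofaces). Under the generated
assignment every non-critical pair cancels instantly: the barcode holds
exactly $\beta_k$ persistent bars per dimension and no finite bars.
Finite bars appear only for externally supplied assignments, and
zero-length bars are suppressed. Barcodes stay on the integer Morse-value
scale; no normalisation is applied.

## Solving for the cavities

For each critical $k$-simplex $c$ the system
$(T\!-\!B_k)\,y = \mathrm{column}(c) \pmod 2$ — tree boundary columns
against the critical column — has a unique solution, because the tree
columns are independent and maximal. The representative cycle is $\{c\}$
plus the tree simplices with $y = 1$ (`solve_cavities_gf2()`), and the
$\beta_k$ representatives form a homology basis, verified by the rank
test $\operatorname{rank}[x_1 \cdots x_{\beta_k} \mid B_{k+1}] =
\beta_k + r_{k+1}$.

The oriented variant (`solve_cavities_oriented()`) uses the signed
boundary matrix, where $(T\!-\!B_{[k]})^{\mathsf T}(T\!-\!B_{[k]})$ *is*
invertible over the rationals, computes the normal-equation solution in
exact fraction arithmetic, and reduces it entrywise mod 2, discarding the
repeated-simplex artifacts of oriented chains. On torsion-free networks
this agrees with the GF(2) solve; in the presence of 2-torsion a reduced
fraction acquires an even denominator and the mod-2 image is refused with
an explicit error — over the rationals that class simply does not exist.

Two refinements operate on a basis:

* `reduce_basis()` shortens representatives by adding (mod 2) boundaries
  of $(k{+}1)$-simplices or peer representatives, restricted to candidates
  sharing more than half of their nodes with the representative
  ("more than half" is read against the candidate's node set), greedy
  best-improvement with lexicographic-first tie-breaks and a default cap
  of 10 iterations per representative. Total length never increases and
  basis rank is preserved.
* `optimal_1_cavities()` searches simple cycles of the 1-skeleton
  exhaustively by increasing length. The search starts at length 3 —
  not 4 — since a 3-cycle left unfilled is a perfectly good cavity; a
  configurable budget on explored paths guards dense networks, returning
  a flagged partial basis when exhausted.

As a cross-check, `hodge_betti()` returns the nullity of the Hodge
Laplacian $L_k = B_k^{\mathsf T} B_k + B_{k+1} B_{k+1}^{\mathsf T}$,
which equals the *rational* Betti number. Since $B_k B_{k+1} = 0$, the
images of the two terms intersect trivially and
$\operatorname{rank}(L_k) = \operatorname{rank}(B_k) +
\operatorname{rank}(B_{k+1})$; the package eliminates the two sparse
$\pm 1$ boundary matrices instead of $L_k$ itself, whose minors overflow
exact double-based fraction arithmetic already at desk scale. The
identity is itself verified in the test suite against direct elimination
of $L_k$ where that is feasible.

## Exactness as a design rule

No tolerance parameter exists anywhere in the package. GF(2) arithmetic
is exact by nature (rows are bit-packed, XOR-reduced in compiled code; a
$3{,}500 \times 2{,}100$ boundary matrix reduces in under two seconds on
one core). Rational arithmetic keeps numerator/denominator pairs in
lowest terms and aborts loudly if an intermediate would exceed $2^{52}$,
rather than silently losing exactness — "zero" always means an
identically zero numerator, never a small float.

## Worked fixtures and what the synthetic data covers

`generate_fixture()` rebuilds, in code, the complexes used throughout the
documentation and tests: the 9-node/27-edge/18-triangle torus
triangulation ($\beta = (1,2,1)$, Morse top value 28, critical values
$\{0, 9, 10, 28\}$, two 3-edge 1-cavities and one 18-triangle 2-cavity);
a 7-node 2-order network with two hand-specified Morse assignments (one
with critical counts $(2,3,1)$, one optimal with two critical simplices);
the octahedron sphere; a hollow triangle; and a 9-vertex grid
triangulation of the Klein bottle. In the published listing of the first
7-node assignment the edge $(1,2)$ appears twice; the only edge missing
from that listing is $(2,3)$, so the second occurrence is read as
$(2,3)$ — the resulting critical sets then match the published ones
exactly.

The Klein bottle is glued from a $3 \times 3$ grid, periodic in one
direction and reflected ($j \mapsto (2-j) \bmod 3$) in the other. A
vertex-minimal (8-vertex) triangulation would serve equally; the grid
construction was chosen because it is generated by a dozen lines of code
and is verifiable by the package itself: GF(2) Betti numbers $(1,2,1)$
against rational Hodge nullities $(1,1,0)$ exhibit the 2-torsion that
separates the two coefficient fields.

`generate_random()` provides seeded generators: a preferential-attachment
network grown from two isolated seed nodes with two edges per arrival
(hence exactly $2(n-2)$ edges — 1,996 at $n = 1{,}000$); Erdős–Rényi
graphs; and noisy circles (uniform angles, isotropic Gaussian noise,
default sd 0.05 on a unit radius). These emulate the degree heterogeneity
and geometric noise of real inputs but not their correlations, weights,
or measurement error structure: a green suite shows the algebra and the
pipeline are right at desk scale, not that any particular biological
network is well approximated.

Test problem sizes are deliberately small — random clique complexes on
6–12 nodes, point clouds of 40–60 points, truncation at order 3 — so the
whole suite exercises every code path, including brute-force oracles
(exhaustive subset ranks, enumerated GF(2) solution sets, exhaustive
clique counts), in seconds. Clique and Rips construction require an
explicit `max_order` because clique enumeration is exponential in the
clique number; truncating at order $k$ leaves $\beta_k$ inflated by
unfillable $k$-cycles, which is the standard trade-off, and the
acceptance analyses therefore only interpret Betti numbers strictly below
the truncation order.

## Known limitations

* A minimal Morse matching with $c_k = \beta_k$ does not exist on every
  complex; the assignment detects the obstruction (queue deadlock) and
  errors instead of degrading gracefully to extra criticals.
* `reduce_basis()` is a heuristic: total length is monotone but not
  guaranteed minimal; provably minimal bases for $k > 1$ are NP-hard and
  out of scope. The exhaustive search is offered for dimension 1 only.
* The oriented solver deliberately refuses 2-torsion classes (even
  denominators) rather than returning something defined over GF(2) only.
* Exact rational elimination aborts above $2^{52}$; for the shipped
  fixtures and desk-scale networks this is never reached, but very dense
  oriented systems may require staying with the GF(2) solver.
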