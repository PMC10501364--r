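# homtree

Persistent homology of simplicial networks by all-order spanning trees
and critical simplices.

Higher-order interactions in biological networks — neuronal connectomes,
brain coactivation graphs, point clouds sampled from shapes — live in the
cliques and cavities of a simplicial complex, not just in its edges.
`homtree` computes these features by a linear-algebraic route: the
*k-order spanning tree* of a complex is a maximal set of k-simplices
whose boundary columns are independent over GF(2), found as the pivot
columns of a row reduction of the boundary matrix `B_k`. With `m_k`
simplices and ranks `r_k`, the Betti numbers and Euler characteristic
follow from rank arithmetic alone:

    beta_k = m_k − r_k − r_{k+1},      chi = Σ (−1)^k m_k = Σ (−1)^k beta_k

Non-tree simplices either pair into the next order's tree or are
*cavity-generating (critical)*; the criticals number exactly `beta_k`,
drive an optimal discrete Morse filtration `K_0 ⊆ … ⊆ K_n` with
`n = r_1 + beta_1 + … + r_l + beta_l`, and index the matrix equation

    (T−B_k) (T−x)^T = (C−B_k)   (mod 2)

whose unique solutions are representative cycles of every cavity. The
package also provides the oriented (exact rational) variant of the solve,
iterative cavity shortening, an exhaustive minimum-length search for
1-cavities, persistence barcodes, and a Hodge-Laplacian nullity
cross-check — all in exact arithmetic, with no tolerance anywhere.

## A worked example

The 9-node, 27-edge, 18-triangle torus triangulation ships as a fixture:

```r
library(homtree)
K <- generate_fixture("torus9")
homology_profile(K)
#> m_k:    9 27 18
#> r_k:    8 17  (k = 1..)
#> beta_k: 1 2 1
#> chi:    0
```

The 1-order spanning tree has the `r_1 = 8` edges
`(1,2) (1,3) (1,4) (1,5) (1,7) (1,9) (2,6) (2,8)`; the critical simplices
are node 1, edges `(2,3)` and `(4,7)`, and triangle `(6,7,9)` — one per
cavity. The induced Morse function tops out at `n = 28` with critical
values `{0, 9, 10, 28}`, and solving the cavity equation returns the
representatives:

```r
solve_cavities_gf2(K, 1)
#> 2 representative 1-cavities, total length 6
#>   [3] {(1,2), (1,3), (2,3)}
#>   [3] {(1,4), (1,7), (4,7)}
solve_cavities_gf2(K, 2)$lengths
#> [1] 18
```

i.e. the two independent 3-edge loops around the torus and the
18-triangle surface itself as the 2-cavity. A shell entry point wraps the
same pipeline (`summary`, `morse`, `barcode`, `cavities`, `fixture`
subcommands):

```sh
Rscript inst/cli/homtree summary --input torus.txt --format simplex_list
```

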