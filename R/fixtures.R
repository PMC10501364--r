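#' Built-in worked-example networks
#'
#' Deterministic fixture generators:
#' \describe{
#'   \item{torus9}{the 9-node, 27-edge, 18-triangle torus triangulation
#'     (explicit simplex list; note it is not a clique complex --- nine
#'     3-cycles of the 1-skeleton are unfilled).}
#'   \item{fig3}{a 7-node, 10-edge, 3-triangle 2-order simplicial network,
#'     returned together with two hand-specified Morse assignments (as
#'     per-order value lists) illustrating a non-optimal (6 critical
#'     simplices) and an optimal-but-different (2 critical simplices)
#'     value choice.}
#'   \item{octahedron}{the boundary of the octahedron: 6 nodes, 12 edges,
#'     8 faces; a triangulated sphere with Betti numbers (1, 0, 1).}
#'   \item{klein_bottle}{a 9-vertex, 18-triangle grid triangulation of the
#'     Klein bottle (one periodic direction, the other glued with a
#'     reflection); GF(2) Betti numbers (1, 2, 1) but rational Hodge
#'     nullities (1, 1, 0), exhibiting 2-torsion.}
#'   \item{hollow_triangle}{the closure of (1,2,3) without the
#'     2-simplex.}
#' }
#'
#' @param name fixture name.
#' @return a `simplicial_network`; for `fig3`, a list with elements
#'   `network`, `first_assignment`, `second_assignment`.
#' @export
generate_fixture <- function(name = c("torus9", "fig3", "octahedron",
                                      "klein_bottle", "hollow_triangle")) {
  name <- match.arg(name)
  switch(name,
         torus9 = build_explicit(.torus9_triangles()),
         fig3 = .fig3_fixture(),
         octahedron = build_explicit(list(
           c(1, 2, 3), c(1, 2, 5), c(1, 3, 4), c(1, 4, 5),
           c(2, 3, 6), c(2, 5, 6), c(3, 4, 6), c(4, 5, 6))),
         klein_bottle = build_explicit(.klein_grid_triangles()),
         hollow_triangle = build_explicit(list(c(1, 2), c(1, 3), c(2, 3))))
}

.torus9_triangles <- function() {
  list(c(1, 2, 5), c(1, 2, 7), c(1, 3, 4), c(1, 3, 9), c(1, 4, 5),
       c(1, 7, 9), c(2, 3, 6), c(2, 3, 8), c(2, 5, 6), c(2, 7, 8),
       c(3, 4, 6), c(3, 8, 9), c(4, 5, 8), c(4, 6, 7), c(4, 7, 8),
       c(5, 6, 9), c(5, 8, 9), c(6, 7, 9))
}

# 3x3 grid on the Klein bottle: columns wrap periodically, the third row
# glues back to the first with the reflection j -> (2 - j) mod 3.
.klein_grid_triangles <- function() {
  v <- function(i, j) {
    j <- j %% 3L
    if (i == 3L) {
      i <- 0L
      j <- (2L - j) %% 3L
    }
    3L * i + j + 1L
  }
  tris <- list()
  for (i in 0:2) {
    for (j in 0:2) {
      a <- v(i, j); b <- v(i, j + 1L); c2 <- v(i + 1L, j); d <- v(i + 1L, j + 1L)
      tris[[length(tris) + 1L]] <- c(a, b, d)
      tris[[length(tris) + 1L]] <- c(a, d, c2)
    }
  }
  tris
}

.fig3_fixture <- function() {
  edges <- list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6),
                c(3, 7), c(3, 6), c(4, 6), c(4, 7), c(2, 6))
  tris <- list(c(4, 5, 6), c(3, 4, 7), c(2, 3, 6))
  K <- build_explicit(c(edges, tris))
  value_list <- function(assignment) {
    lapply(0:K$max_order, function(k) {
      keys <- simplex_keys(K, k)
      v <- assignment[keys]
      if (anyNA(v)) stop("fixture assignment misses a simplex")
      unname(v)
    })
  }
  # the published listing duplicates edge (1,2); the only unlisted edge is
  # (2,3), so its second occurrence is read as (2,3)
  first <- c("1" = 0, "2" = 1, "3" = 2, "4" = 3, "5" = 4, "6" = 5, "7" = 8,
             "1,2" = 1, "3,4" = 3, "4,5" = 4, "5,6" = 5, "2,3" = 6,
             "4,6" = 7, "3,7" = 8, "4,7" = 9, "3,6" = 10, "2,6" = 11,
             "4,5,6" = 7, "2,3,6" = 11, "3,4,7" = 12)
  second <- c("1" = 0, "2" = 1, "3" = 2, "4" = 3, "5" = 4, "6" = 5, "7" = 6,
              "1,2" = 1, "2,3" = 2, "3,4" = 3, "4,5" = 4, "5,6" = 5,
              "3,7" = 6, "3,6" = 7, "4,6" = 8, "4,7" = 9, "2,6" = 10,
              "4,5,6" = 8, "3,4,7" = 9, "2,3,6" = 10)
  list(network = K,
       first_assignment = value_list(first),
       second_assignment = value_list(second))
}

#' Seeded random networks and point clouds
#'
#' \describe{
#'   \item{ba_model}{preferential-attachment (Barabasi-Albert) graph:
#'     growth starts from two isolated nodes; the first arrival joins
#'     both, and every later arriving node attaches 2 edges to distinct
#'     existing nodes with probability proportional to degree, giving
#'     exactly `2(n - 2)` edges (1,996 at n = 1,000).}
#'   \item{er_graph}{Erdos-Renyi G(n, p) graph.}
#'   \item{noisy_circle}{n points on the unit circle with isotropic
#'     Gaussian coordinate noise.}
#' }
#' All generators are deterministic given `seed`; the caller's random
#' number generator state is left untouched.
#'
#' @param kind generator name.
#' @param n number of nodes / points.
#' @param seed mandatory integer seed.
#' @param p edge probability (`er_graph`).
#' @param noise coordinate noise standard deviation (`noisy_circle`).
#' @return for graphs, a two-column edge-list matrix of node labels; for
#'   `noisy_circle`, an n x 2 coordinate matrix.
#' @export
generate_random <- function(kind = c("ba_model", "er_graph", "noisy_circle"),
                            n, seed, p = 0.5, noise = 0.05) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(n), n >= 2, is.numeric(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  switch(kind,
         ba_model = .ba_growth(as.integer(n)),
         er_graph = {
           g <- igraph::sample_gnp(n, p)
           el <- igraph::as_edgelist(g)
           if (nrow(el) == 0L) el <- matrix(numeric(0), 0L, 2L)
           el
         },
         noisy_circle = {
           theta <- stats::runif(n, 0, 2 * pi)
           cbind(cos(theta), sin(theta)) +
             matrix(stats::rnorm(2 * n, sd = noise), ncol = 2L)
         })
}

.ba_growth <- function(n) {
  stopifnot(n >= 3L)
  deg <- integer(n)
  from <- integer(2L * (n - 2L))
  to <- integer(2L * (n - 2L))
  e <- 0L
  for (t in 3:n) {
    targets <- if (t == 3L) 1:2 else {
      sample(t - 1L, 2L, prob = deg[seq_len(t - 1L)])
    }
    for (w in targets) {
      e <- e + 1L
      from[e] <- w
      to[e] <- t
      deg[w] <- deg[w] + 1L
    }
    deg[t] <- 2L
  }
  cbind(from, to, deparse.level = 0L)
}
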