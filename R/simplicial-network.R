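#' Simplicial networks
#'
#' A simplicial network is the collection of all simplices of all orders of
#' a simplicial complex: nodes (0-simplices), edges (1-simplices), filled
#' triangles (2-simplices), and so on, closed under taking faces. Vertices
#' carry arbitrary labels; internally they are mapped to dense 1-based
#' indices in sorted label order, and every simplex is stored as its
#' strictly increasing vertex tuple. Within each order the simplices are
#' kept in lexicographic order of their vertex tuples, which fixes all
#' boundary-matrix row and column orders and makes pivot choices
#' deterministic.
#'
#' @name simplicial_network
NULL

.lex_order <- function(m) {
  if (nrow(m) <= 1L) return(seq_len(nrow(m)))
  do.call(order, lapply(seq_len(ncol(m)), function(j) m[, j]))
}

.simplex_keys <- function(m, labels) {
  if (nrow(m) == 0L) return(character(0))
  apply(m, 1L, function(r) paste(labels[r], collapse = ","))
}

# simplices: list by order of integer matrices (rows = simplices, strictly
# increasing internal vertex indices); labels: sorted original labels.
.new_network <- function(simplices, labels, birth = NULL) {
  simplices <- lapply(simplices, function(m) {
    m <- m[.lex_order(m), , drop = FALSE]
    rownames(m) <- NULL
    m
  })
  counts <- vapply(simplices, nrow, integer(1))
  structure(list(simplices = simplices,
                 labels = labels,
                 counts = counts,
                 max_order = length(simplices) - 1L,
                 birth = birth),
            class = "simplicial_network")
}

#' @export
print.simplicial_network <- function(x, ...) {
  cat("simplicial network:", length(x$labels), "vertices, max order",
      x$max_order, "\n")
  if (x$max_order >= 0L) {
    cat("simplex counts m_k:", paste(x$counts, collapse = " "), "\n")
  }
  invisible(x)
}

#' Simplex counts of a network
#'
#' @param K a `simplicial_network`.
#' @return integer vector `m_k`, `k = 0..max_order`.
#' @export
simplex_counts <- function(K) {
  stopifnot(inherits(K, "simplicial_network"))
  K$counts
}

#' Simplices of one order, with original labels
#'
#' @param K a `simplicial_network`.
#' @param k order.
#' @return matrix with `k + 1` columns of vertex labels, rows in the
#'   network's lexicographic order.
#' @export
simplices <- function(K, k) {
  stopifnot(inherits(K, "simplicial_network"), k >= 0L, k <= K$max_order)
  m <- K$simplices[[k + 1L]]
  matrix(K$labels[m], nrow = nrow(m))
}

#' Simplex keys (comma-joined label tuples) of one order
#'
#' @inheritParams simplices
#' @return character vector of keys such as `"1,2,5"`.
#' @export
simplex_keys <- function(K, k) {
  stopifnot(inherits(K, "simplicial_network"), k >= 0L, k <= K$max_order)
  .simplex_keys(K$simplices[[k + 1L]], K$labels)
}

# Face closure of a set of top simplices given as a list of integer index
# vectors (already strictly increasing). Returns list by order of matrices.
.face_closure <- function(tuples) {
  if (length(tuples) == 0L) return(list())
  maxk <- max(vapply(tuples, length, integer(1))) - 1L
  by_order <- vector("list", maxk + 1L)
  pool <- lapply(tuples, as.integer)
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  rows <- vector("list", maxk + 1L)
  for (i in seq_along(rows)) rows[[i]] <- list()
  while (length(pool)) {
    nxt <- list()
    for (s in pool) {
      key <- paste(s, collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      k <- length(s) - 1L
      rows[[k + 1L]][[length(rows[[k + 1L]]) + 1L]] <- s
      if (k > 0L) {
        for (p in seq_along(s)) nxt[[length(nxt) + 1L]] <- s[-p]
      }
    }
    pool <- nxt
  }
  for (k in 0:maxk) {
    by_order[[k + 1L]] <- matrix(unlist(rows[[k + 1L]]),
                                 ncol = k + 1L, byrow = TRUE)
  }
  by_order
}

.normalize_tuples <- function(top_simplices) {
  if (is.matrix(top_simplices)) {
    top_simplices <- lapply(seq_len(nrow(top_simplices)),
                            function(i) top_simplices[i, ])
  }
  lapply(top_simplices, function(s) {
    s <- s[!is.na(s)]
    if (anyDuplicated(s)) stop("simplex with repeated vertex: ",
                               paste(s, collapse = ","))
    s
  })
}

#' Build a simplicial network as the face closure of explicit simplices
#'
#' No clique completion is performed: the network contains exactly the given
#' simplices and all of their faces. This is the constructor for
#' triangulations that are not clique complexes, such as the 9-node torus
#' whose 18 triangles coexist with unfilled 3-cycles.
#'
#' @param top_simplices list of vertex-label vectors (or a matrix, one
#'   simplex per row). Duplicates are removed; an empty list yields the
#'   empty network.
#' @return a `simplicial_network`.
#' @examples
#' K <- build_explicit(list(c(1, 2, 3)))
#' simplex_counts(K) # 3 3 1
#' @export
build_explicit <- function(top_simplices) {
  tuples <- .normalize_tuples(top_simplices)
  if (length(tuples) == 0L) {
    return(.new_network(list(), labels = character(0)))
  }
  labels <- sort(unique(unlist(lapply(tuples, as.character))))
  idx <- lapply(tuples, function(s) sort(match(as.character(s), labels)))
  lab <- unlist(lapply(tuples, as.character))
  labels <- .restore_label_type(labels, lab)
  .new_network(.face_closure(idx), labels)
}

# keep numeric labels numeric (sorted numerically) when all parse as numbers
.restore_label_type <- function(labels, raw) {
  num <- suppressWarnings(as.numeric(labels))
  if (!anyNA(num)) sort(num) else labels
}

.label_index <- function(labels, x) {
  i <- match(as.character(x), as.character(labels))
  if (anyNA(i)) stop("unknown vertex label: ", paste(x[is.na(i)], collapse = ","))
  i
}

#' Build the clique complex of a graph
#'
#' Every (k+1)-clique of the graph with `k <= max_order` becomes a
#' k-simplex; closure under faces holds by construction. This is how a
#' conventional network (for example a connectome) is promoted to a
#' simplicial network.
#'
#' @param x a symmetric 0/1 adjacency matrix with zero diagonal (optionally
#'   with labels as dimnames), or a two-column edge list (matrix or data
#'   frame of vertex labels).
#' @param max_order highest simplex order to enumerate. Required: clique
#'   enumeration is exponential in the clique number, so the cap must be an
#'   explicit choice.
#' @return a `simplicial_network`.
#' @examples
#' adj <- matrix(1, 3, 3) - diag(3) # triangle graph
#' simplex_counts(build_clique_complex(adj, max_order = 2)) # 3 3 1
#' @export
build_clique_complex <- function(x, max_order) {
  stopifnot(is.numeric(max_order), max_order >= 0L)
  g <- .as_graph(x)
  labels <- igraph::V(g)$name
  cl <- igraph::cliques(g, min = 1L, max = max_order + 1L)
  tuples <- lapply(cl, function(v) sort(as.integer(v)))
  labels2 <- sort(unique(unlist(lapply(tuples, function(s) labels[s]))))
  labels2 <- .restore_label_type(labels2, labels)
  idx <- lapply(tuples, function(s) sort(match(labels[s], as.character(labels2))))
  maxk <- max(vapply(idx, length, integer(1))) - 1L
  by_order <- vector("list", maxk + 1L)
  for (k in 0:maxk) {
    rows <- idx[vapply(idx, length, integer(1)) == k + 1L]
    by_order[[k + 1L]] <- matrix(unlist(rows), ncol = k + 1L, byrow = TRUE)
  }
  .new_network(by_order, labels2)
}

.as_graph <- function(x) {
  if (is.data.frame(x)) x <- matrix(as.character(as.matrix(x)), nrow(x))
  # a numeric square 0/1 matrix is an adjacency matrix; anything two-column
  # (labels, or numeric with non-binary entries) is an edge list
  is_adj <- is.matrix(x) && is.numeric(x) && nrow(x) == ncol(x) &&
    all(x == 0 | x == 1)
  if (is.matrix(x) && !is_adj && ncol(x) == 2L) {
    ends <- matrix(as.character(x), ncol = 2L)
    if (any(ends[, 1L] == ends[, 2L])) stop("self-loop in edge list")
    labels <- sort(unique(as.vector(ends)))
    g <- igraph::graph_from_edgelist(ends, directed = FALSE)
    g <- igraph::simplify(g)
    miss <- setdiff(labels, igraph::V(g)$name)
    if (length(miss)) g <- igraph::add_vertices(g, length(miss), name = miss)
    return(g)
  }
  if (is_adj) {
    if (!isSymmetric(unname(x))) stop("adjacency matrix must be symmetric")
    if (any(diag(x) != 0)) stop("self-loop: nonzero diagonal in adjacency matrix")
    if (any(x != 0 & x != 1)) stop("adjacency entries must be 0 or 1")
    labels <- rownames(x)
    if (is.null(labels)) labels <- as.character(seq_len(nrow(x)))
    dimnames(x) <- list(labels, labels)
    return(igraph::graph_from_adjacency_matrix(x, mode = "undirected"))
  }
  stop("expected an adjacency matrix or a two-column edge list")
}

#' Build a Vietoris-Rips complex from a point cloud
#'
#' Connects every pair of points at Euclidean distance at most `threshold`
#' and takes the clique complex of the resulting graph. Each simplex is
#' annotated with its birth value: the largest pairwise distance among its
#' vertices (0 for a node), i.e. the smallest threshold at which the
#' simplex appears.
#'
#' @param points numeric matrix, one point per row.
#' @param threshold distance threshold (>= 0).
#' @param max_order highest simplex order to enumerate.
#' @return a `simplicial_network` whose `birth` field holds, per order, the
#'   birth value of each simplex (aligned with the lexicographic simplex
#'   order).
#' @export
build_rips <- function(points, threshold, max_order) {
  points <- as.matrix(points)
  if (!is.numeric(points) || anyNA(points)) {
    stop("point cloud must be numeric with no missing coordinates")
  }
  stopifnot(threshold >= 0)
  n <- nrow(points)
  D <- as.matrix(dist(points))
  adj <- (D <= threshold) * 1
  diag(adj) <- 0
  rownames(adj) <- colnames(adj) <- format(seq_len(n), trim = TRUE,
                                           scientific = FALSE)
  K <- build_clique_complex(adj, max_order = max_order)
  # labels sort as characters of point indices; map back to point rows
  pt <- .label_index_points(K$labels, n)
  birth <- lapply(seq_along(K$simplices), function(oi) {
    m <- K$simplices[[oi]]
    if (ncol(m) == 1L) return(rep(0, nrow(m)))
    apply(m, 1L, function(s) {
      v <- pt[s]
      max(D[v, v][upper.tri(D[v, v])])
    })
  })
  K$labels <- pt  # report point indices as numeric labels
  K2 <- .new_network(K$simplices, pt, birth = birth)
  K2
}

.label_index_points <- function(labels, n) {
  as.integer(labels)
}

#' Boundary matrix of a simplicial network
#'
#' Incidence matrix between the (k-1)-simplices (rows) and the k-simplices
#' (columns), in the network's lexicographic simplex order. In the
#' unoriented view an entry is 1 iff the row simplex is a face of the
#' column simplex. In the oriented view the face obtained by deleting the
#' vertex in position `p` (0-based) of the increasing vertex tuple carries
#' sign `(-1)^p`.
#'
#' @param K a `simplicial_network`.
#' @param k order, `1 <= k <= max_order`.
#' @param oriented logical; select the signed view.
#' @return integer matrix with simplex keys as dimnames.
#' @export
boundary_matrix <- function(K, k, oriented = FALSE) {
  stopifnot(inherits(K, "simplicial_network"))
  if (!(k >= 1L && k <= K$max_order)) {
    stop("order k must satisfy 1 <= k <= ", K$max_order)
  }
  rows <- K$simplices[[k]]
  cols <- K$simplices[[k + 1L]]
  rk <- .simplex_keys(rows, seq_along(K$labels))
  lookup <- seq_len(nrow(rows))
  names(lookup) <- rk
  B <- matrix(0L, nrow(rows), nrow(cols))
  for (j in seq_len(nrow(cols))) {
    s <- cols[j, ]
    for (p in seq_along(s)) {
      face <- paste(s[-p], collapse = ",")
      i <- lookup[[face]]
      B[i, j] <- if (oriented) as.integer((-1L)^(p - 1L)) else 1L
    }
  }
  dimnames(B) <- list(.simplex_keys(rows, K$labels),
                      .simplex_keys(cols, K$labels))
  B
}

#' Ranks, Betti numbers and Euler characteristic
#'
#' Computes the GF(2) rank `r_k` of every boundary matrix (the size of the
#' k-order spanning tree), the Betti numbers `beta_k = m_k - r_k - r_{k+1}`
#' (with `r_0 = 0` and `r_{l+1} = 0` by convention), and the Euler
#' characteristic `chi = sum (-1)^k m_k = sum (-1)^k beta_k`.
#'
#' @param K a `simplicial_network`.
#' @return an object of class `homology_profile`: list with `m`, `r`
#'   (named by order `1..l`), `betti` (named `0..l`), and `euler`.
#' @examples
#' K <- generate_fixture("torus9")
#' homology_profile(K) # r = (8, 17), beta = (1, 2, 1), chi = 0
#' @export
homology_profile <- function(K) {
  stopifnot(inherits(K, "simplicial_network"))
  l <- K$max_order
  if (l < 0L) {
    return(structure(list(m = integer(0), r = integer(0),
                          betti = integer(0), euler = 0L),
                     class = "homology_profile"))
  }
  m <- K$counts
  r <- integer(l)
  if (l >= 1L) {
    for (k in seq_len(l)) {
      r[k] <- gf2_reduce(boundary_matrix(K, k))$rank
    }
  }
  rpad <- c(0L, r, 0L) # r_0 .. r_{l+1}
  betti <- vapply(0:l, function(k) m[k + 1L] - rpad[k + 1L] - rpad[k + 2L],
                  integer(1))
  chi <- sum((-1L)^(0:l) * m)
  structure(list(m = m,
                 r = if (l >= 1L) stats::setNames(r, seq_len(l)) else integer(0),
                 betti = stats::setNames(betti, 0:l),
                 euler = chi),
            class = "homology_profile")
}

#' @export
print.homology_profile <- function(x, ...) {
  cat("m_k:   ", paste(x$m, collapse = " "), "\n")
  cat("r_k:   ", paste(x$r, collapse = " "), " (k = 1..)\n")
  cat("beta_k:", paste(x$betti, collapse = " "), "\n")
  cat("chi:   ", x$euler, "\n")
  invisible(x)
}
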