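.new_cavity_basis <- function(K, k, supports, complete = TRUE) {
  supports <- lapply(supports, function(s) sort(as.integer(s)))
  keys <- simplex_keys(K, k)
  structure(list(order = k,
                 supports = supports,
                 members = lapply(supports, function(s) keys[s]),
                 lengths = lengths(supports),
                 total_length = sum(lengths(supports)),
                 complete = complete),
            class = "cavity_basis")
}

#' @export
print.cavity_basis <- function(x, ...) {
  cat(length(x$supports), " representative ", x$order, "-cavities, total length ",
      x$total_length, "\n", sep = "")
  for (i in seq_along(x$members)) {
    cat("  [", x$lengths[i], "] {",
        paste0("(", x$members[[i]], ")", collapse = ", "), "}\n", sep = "")
  }
  invisible(x)
}

.cycle_check <- function(K, k, supports) {
  if (length(supports) == 0L) return(invisible(TRUE))
  B <- boundary_matrix(K, k)
  for (s in supports) {
    x <- integer(ncol(B))
    x[s] <- 1L
    if (any((B %*% x) %% 2L != 0L)) {
      stop("solved ", k, "-cavity is not a mod-2 cycle")
    }
  }
  invisible(TRUE)
}

#' Solve the spanning-tree/critical-simplex equation over GF(2)
#'
#' For each cavity-generating k-simplex c, the system
#' `(T-B_k) y = column(c) (mod 2)` --- tree boundary columns on the left,
#' the critical column on the right --- has a unique solution because the
#' tree columns are independent and maximal. The cavity representative is
#' `{c}` together with the tree simplices where `y = 1`; the `beta_k`
#' representatives form a homology basis.
#'
#' @param K a `simplicial_network`.
#' @param k cavity order, `1 <= k <= max_order`.
#' @param classification optional [classify_simplices()] result (computed
#'   if missing); alternatively pass `tree` and `criticals` directly.
#' @param tree,criticals optional explicit index vectors of the k-order
#'   tree members and the critical k-simplices.
#' @return an object of class `cavity_basis`: list with `order`,
#'   `supports` (index vectors into the k-simplex list), `members` (the
#'   same as label keys), `lengths`, and `total_length`.
#' @examples
#' solve_cavities_gf2(generate_fixture("torus9"), 1)
#' # {(1,2), (1,3), (2,3)} and {(1,4), (1,7), (4,7)}
#' @export
solve_cavities_gf2 <- function(K, k, classification = NULL,
                               tree = NULL, criticals = NULL) {
  stopifnot(inherits(K, "simplicial_network"), k >= 1L, k <= K$max_order)
  if (is.null(tree) || is.null(criticals)) {
    if (is.null(classification)) classification <- classify_simplices(K)
    tree <- classification$tree[[k + 1L]]
    criticals <- classification$critical[[k + 1L]]
  }
  B <- boundary_matrix(K, k)
  if (length(criticals) == 0L) return(.new_cavity_basis(K, k, list()))
  A <- B[, tree, drop = FALSE]
  C <- B[, criticals, drop = FALSE]
  X <- gf2_solve(A, C)
  supports <- lapply(seq_along(criticals), function(j) {
    c(criticals[j], tree[X[, j] == 1L])
  })
  .cycle_check(K, k, supports)
  .new_cavity_basis(K, k, supports)
}

#' Solve the oriented cavity equation by exact rational least squares
#'
#' Uses the signed boundary matrix: with `A` the oriented tree columns and
#' `C` the oriented critical columns, `(A'A)` is invertible over the
#' rationals, so `X = (A'A)^{-1} A'C` is computed exactly (see
#' [rational_normal_solve()]) and then reduced entrywise mod 2, which
#' removes the repeated-simplex artifacts of oriented chains. The mod-2
#' supports satisfy the GF(2) cycle condition and agree with
#' [solve_cavities_gf2()].
#'
#' @inheritParams solve_cavities_gf2
#' @return a `cavity_basis`.
#' @export
solve_cavities_oriented <- function(K, k, classification = NULL,
                                    tree = NULL, criticals = NULL) {
  stopifnot(inherits(K, "simplicial_network"), k >= 1L, k <= K$max_order)
  if (is.null(tree) || is.null(criticals)) {
    if (is.null(classification)) classification <- classify_simplices(K)
    tree <- classification$tree[[k + 1L]]
    criticals <- classification$critical[[k + 1L]]
  }
  if (length(criticals) == 0L) return(.new_cavity_basis(K, k, list()))
  Bo <- boundary_matrix(K, k, oriented = TRUE)
  X <- rational_normal_solve(Bo[, tree, drop = FALSE],
                             Bo[, criticals, drop = FALSE])
  Xm <- rational_mod2(X)
  supports <- lapply(seq_along(criticals), function(j) {
    c(criticals[j], tree[Xm[, j] == 1L])
  })
  .cycle_check(K, k, supports)
  .new_cavity_basis(K, k, supports)
}

#' Length distribution of a cavity basis
#'
#' @param basis a `cavity_basis`.
#' @return list with `counts` (a named integer vector, length -> number of
#'   representatives) and `total_length`.
#' @export
length_distribution <- function(basis) {
  stopifnot(inherits(basis, "cavity_basis"))
  if (length(basis$lengths) == 0L) {
    return(list(counts = integer(0), total_length = 0L))
  }
  tab <- table(basis$lengths)
  list(counts = stats::setNames(as.integer(tab), names(tab)),
       total_length = basis$total_length)
}

#' Rank-independence check of a cavity basis
#'
#' A valid homology basis must be independent modulo boundaries: the GF(2)
#' rank of the indicator columns together with `B_{k+1}` must equal
#' `beta_k + r_{k+1}`.
#'
#' @param basis a `cavity_basis`.
#' @param K the network the basis was computed on.
#' @return `TRUE` or `FALSE`.
#' @export
cavity_independence <- function(basis, K) {
  stopifnot(inherits(basis, "cavity_basis"), inherits(K, "simplicial_network"))
  k <- basis$order
  mk <- K$counts[k + 1L]
  ind <- vapply(basis$supports, function(s) {
    x <- integer(mk)
    x[s] <- 1L
    x
  }, integer(mk))
  if (length(basis$supports) == 0L) ind <- matrix(0L, mk, 0L)
  Bup <- if (k < K$max_order) boundary_matrix(K, k + 1L) else
    matrix(0L, mk, 0L)
  r_up <- if (ncol(Bup)) gf2_reduce(Bup)$rank else 0L
  M <- cbind(ind, Bup)
  gf2_reduce(M)$rank == length(basis$supports) + r_up
}

.symdiff <- function(a, b) {
  v <- sort(c(a, b))
  v[!(duplicated(v) | duplicated(v, fromLast = TRUE))]
}

.node_set <- function(K, k, support) {
  sort(unique(as.vector(K$simplices[[k + 1L]][support, , drop = FALSE])))
}

#' Shorten cavity representatives by iterated cycle addition
#'
#' Each representative is repeatedly replaced by its mod-2 sum (symmetric
#' difference of supports) with a candidate cycle, whenever that sum is
#' strictly shorter. Candidates are the boundaries of (k+1)-simplices of
#' the network (class-preserving) and the other representatives of the
#' basis (class-mixing but basis-preserving), restricted to candidates
#' sharing more than half of their nodes with the representative. Greedy
#' best-improvement; ties go to the earliest candidate (boundaries in
#' lexicographic order first, then peers). Total length never increases
#' and the basis rank is preserved.
#'
#' @param basis a `cavity_basis`.
#' @param K the network the basis was computed on.
#' @param max_iter iteration cap per representative.
#' @return a shortened `cavity_basis`.
#' @export
reduce_basis <- function(basis, K, max_iter = 10L) {
  stopifnot(inherits(basis, "cavity_basis"), inherits(K, "simplicial_network"))
  k <- basis$order
  supports <- basis$supports
  if (length(supports) == 0L) return(basis)
  bnd <- list()
  if (k < K$max_order) {
    B <- boundary_matrix(K, k + 1L)
    bnd <- lapply(seq_len(ncol(B)), function(j) which(B[, j] == 1L))
  }
  bnd_nodes <- lapply(bnd, function(s) .node_set(K, k, s))
  for (i in seq_along(supports)) {
    for (iter in seq_len(max_iter)) {
      rep_s <- supports[[i]]
      rep_nodes <- .node_set(K, k, rep_s)
      best <- NULL
      best_len <- length(rep_s)
      consider <- function(cand, cand_nodes) {
        if (length(intersect(cand_nodes, rep_nodes)) * 2L <=
            length(cand_nodes)) return(NULL)
        merged <- .symdiff(rep_s, cand)
        if (length(merged) > 0L && length(merged) < best_len) merged else NULL
      }
      for (b in seq_along(bnd)) {
        merged <- consider(bnd[[b]], bnd_nodes[[b]])
        if (!is.null(merged)) {
          best <- merged
          best_len <- length(merged)
        }
      }
      for (j in seq_along(supports)) {
        if (j == i) next
        merged <- consider(supports[[j]], .node_set(K, k, supports[[j]]))
        if (!is.null(merged)) {
          best <- merged
          best_len <- length(merged)
        }
      }
      if (is.null(best)) break
      supports[[i]] <- best
    }
  }
  out <- .new_cavity_basis(K, k, supports)
  .cycle_check(K, k, supports)
  out
}

#' Exhaustive search for optimal 1-order cavities
#'
#' Starting at cycle length 3 and increasing, enumerates simple cycles of
#' the 1-skeleton through each remaining critical edge and accepts a cycle
#' if it is independent of the previously accepted ones modulo the image
#' of `B_2` (a GF(2) rank test). The search stops when `beta_1` cavities
#' are found, yielding a homology basis of minimum total length.
#'
#' @param K a `simplicial_network`.
#' @param criticals optional index vector of critical edges (from
#'   [classify_simplices()] if missing).
#' @param budget maximum number of partial paths explored before the
#'   search is abandoned with a warning (guards dense networks).
#' @return a `cavity_basis`; when the budget is exhausted the element
#'   `complete` is `FALSE` and only the cavities found so far are
#'   returned.
#' @export
optimal_1_cavities <- function(K, criticals = NULL, budget = 1e6) {
  stopifnot(inherits(K, "simplicial_network"), K$max_order >= 1L)
  if (is.null(criticals)) criticals <- classify_simplices(K)$critical[[2L]]
  if (length(criticals) == 0L) return(.new_cavity_basis(K, 1L, list()))
  edges <- K$simplices[[2L]]
  m1 <- nrow(edges)
  nv <- length(K$labels)
  adj <- vector("list", nv)
  edge_id <- new.env(parent = emptyenv(), hash = TRUE)
  for (e in seq_len(m1)) {
    a <- edges[e, 1L]; b <- edges[e, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
    edge_id[[paste(a, b)]] <- e
  }
  adj <- lapply(adj, sort)
  eid <- function(a, b) edge_id[[paste(min(a, b), max(a, b))]]
  Bup <- if (K$max_order >= 2L) boundary_matrix(K, 2L) else matrix(0L, m1, 0L)
  base_rank <- if (ncol(Bup)) gf2_reduce(Bup)$rank else 0L
  accepted <- list()
  acc_mat <- matrix(0L, m1, 0L)
  indep <- function(s) {
    x <- integer(m1); x[s] <- 1L
    gf2_reduce(cbind(Bup, acc_mat, x))$rank ==
      base_rank + ncol(acc_mat) + 1L
  }
  remaining <- sort(criticals)
  steps <- 0L
  out_of_budget <- FALSE
  for (L in 3:max(3L, nv)) {
    if (length(remaining) == 0L || out_of_budget) break
    for (ci in seq_along(remaining)) {
      if (out_of_budget) break
      ce <- remaining[[ci]]
      if (is.na(ce)) next
      u <- edges[ce, 1L]; v <- edges[ce, 2L]
      found <- NULL
      # simple paths v -> u of L-1 edges; closed by the critical edge (u,v)
      dfs <- function(at, path_nodes, path_edges) {
        if (!is.null(found) || out_of_budget) return()
        steps <<- steps + 1L
        if (steps > budget) {
          out_of_budget <<- TRUE
          return()
        }
        if (length(path_edges) == L - 1L) {
          if (at == u) {
            s <- sort(c(ce, path_edges))
            if (indep(s)) found <<- s
          }
          return()
        }
        for (w in adj[[at]]) {
          if (w == u) { # close the cycle only as the final step
            if (length(path_edges) == L - 2L) {
              dfs(w, path_nodes, c(path_edges, eid(at, w)))
            }
            next
          }
          if (w %in% path_nodes) next
          dfs(w, c(path_nodes, w), c(path_edges, eid(at, w)))
        }
      }
      dfs(v, c(u, v), integer(0))
      if (!is.null(found)) {
        accepted[[length(accepted) + 1L]] <- found
        x <- integer(m1); x[found] <- 1L
        acc_mat <- cbind(acc_mat, x)
        remaining[ci] <- NA_integer_
      }
    }
    remaining <- remaining[!is.na(remaining)]
  }
  if (out_of_budget) {
    warning("optimal_1_cavities: search budget exhausted; returning the ",
            length(accepted), " cavities found so far")
  }
  .cycle_check(K, 1L, accepted)
  .new_cavity_basis(K, 1L, accepted, complete = length(remaining) == 0L)
}

#' Betti number via the Hodge Laplacian
#'
#' The Hodge Laplacian `L_k = B_k' B_k + B_{k+1} B_{k+1}'` is assembled
#' from the oriented boundary matrices over the integers; its nullity
#' `m_k - rank(L_k)` equals the rational Betti number, which matches the
#' GF(2) Betti number on torsion-free networks and differs in the presence
#' of 2-torsion (e.g. a Klein bottle). The rank is obtained by exact
#' rational elimination (no eigensolver, no tolerance): since
#' `B_k B_{k+1} = 0`, the images of the two Laplacian terms intersect
#' trivially, so `rank(L_k) = rank(B_k) + rank(B_{k+1})` over the
#' rationals, and eliminating the two (sparse, entries in -1/0/1) boundary
#' matrices avoids the huge minors of `L_k` itself.
#'
#' @param K a `simplicial_network`.
#' @param k order, `0 <= k <= max_order`.
#' @return integer nullity of `L_k`.
#' @export
hodge_betti <- function(K, k) {
  stopifnot(inherits(K, "simplicial_network"), k >= 0L, k <= K$max_order)
  mk <- K$counts[k + 1L]
  r_down <- if (k >= 1L) {
    rational_rank(boundary_matrix(K, k, oriented = TRUE))
  } else 0L
  r_up <- if (k < K$max_order) {
    rational_rank(boundary_matrix(K, k + 1L, oriented = TRUE))
  } else 0L
  as.integer(mk - r_down - r_up)
}
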