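#' k-order spanning tree of a simplicial network
#'
#' A k-order spanning tree is a maximal set of k-simplices whose boundary
#' columns are linearly independent over GF(2); its size is the rank `r_k`
#' of the boundary matrix. It is found by row-reducing `B_k` with
#' lexicographic column order (the tree members are the pivot columns, and
#' they do not depend on the row scan order).
#'
#' @param K a `simplicial_network`.
#' @param k order, `1 <= k <= max_order`.
#' @return an object of class `spanning_tree`: list with `order`, `indices`
#'   (sorted positions of the members in the network's k-simplex list),
#'   `keys`, and `size` (= `r_k`).
#' @examples
#' tr <- spanning_tree(generate_fixture("torus9"), 1)
#' tr$keys # the 8 tree edges (1,2) (1,3) (1,4) (1,5) (1,7) (1,9) (2,6) (2,8)
#' @export
spanning_tree <- function(K, k) {
  red <- gf2_reduce(boundary_matrix(K, k))
  idx <- sort(red$pivot_cols)
  structure(list(order = k,
                 indices = idx,
                 keys = simplex_keys(K, k)[idx],
                 size = red$rank),
            class = "spanning_tree")
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat(x$order, "-order spanning tree with ", x$size, " simplices\n", sep = "")
  cat(paste(x$keys, collapse = "  "), "\n")
  invisible(x)
}

#' Classify every simplex as tree, paired, or cavity-generating
#'
#' For each order k the simplices split into exactly three roles:
#' \describe{
#'   \item{tree}{members of the k-order spanning tree (`r_k` of them);}
#'   \item{paired}{non-tree simplices matched as pivot rows into the
#'     (k+1)-order spanning tree during the reduction of `B_{k+1}`
#'     (`r_{k+1}` of them), each paired with the (k+1)-tree simplex of its
#'     pivot column;}
#'   \item{critical}{the remaining `beta_k` cavity-generating simplices:
#'     adding one creates a new homology class.}
#' }
#'
#' The reduction of `B_{k+1}` scans rows bottom-up (reverse lexicographic)
#' with all non-tree rows before tree rows, preferring rows that are faces
#' of the pivot column's simplex. Boundary columns are cycles and cycles
#' are determined by their non-tree coordinates, so every pivot lands on a
#' non-tree row; this forces the per-order critical count to equal
#' `beta_k`. At order 0 the critical simplices are one start node per
#' connected component (by default the smallest label, which bottom-up
#' pivoting leaves unmatched).
#'
#' @param K a `simplicial_network`.
#' @param start_nodes optional vector of vertex labels, one per connected
#'   component, to serve as the order-0 critical simplices.
#' @return an object of class `simplex_classification`: lists (indexed by
#'   order k + 1) `roles` (character vectors aligned with the simplex
#'   lists), `tree`, `paired`, `critical` (index vectors), `partner_up`
#'   (paired k-simplex index -> partner (k+1)-simplex index, `NA`
#'   otherwise), `partner_down` (tree k-simplex -> its paired (k-1)-face),
#'   plus the `homology_profile`-style `r` and `betti`.
#' @examples
#' cls <- classify_simplices(generate_fixture("torus9"))
#' vapply(cls$critical, length, integer(1)) # 1 2 1 = the Betti numbers
#' @export
classify_simplices <- function(K, start_nodes = NULL) {
  stopifnot(inherits(K, "simplicial_network"))
  l <- K$max_order
  if (l < 0L) {
    return(structure(list(roles = list(), tree = list(), paired = list(),
                          critical = list(), partner_up = list(),
                          partner_down = list(), r = integer(0),
                          betti = integer(0)),
                     class = "simplex_classification"))
  }
  m <- K$counts
  roles <- lapply(m, function(n) rep("critical", n))
  partner_up <- lapply(m, function(n) rep(NA_integer_, n))
  partner_down <- lapply(m, function(n) rep(NA_integer_, n))
  tree <- vector("list", l + 1L)
  paired <- vector("list", l + 1L)
  for (i in seq_len(l + 1L)) {
    tree[[i]] <- integer(0)
    paired[[i]] <- integer(0)
  }
  r <- integer(l)
  prev_tree <- integer(0) # there is no 0-order tree
  for (k in seq_len(l)) {
    B <- boundary_matrix(K, k)
    nrows <- m[k]
    nontree <- setdiff(seq_len(nrows), prev_tree)
    prio <- c(rev(nontree), rev(prev_tree))
    preferable <- nontree
    if (k == 1L && !is.null(start_nodes)) {
      sn <- .label_index(K$labels, start_nodes)
      prio <- c(setdiff(prio, sn), sn) # start nodes pivot only as last resort
      preferable <- setdiff(preferable, sn)
    }
    prefer <- lapply(seq_len(ncol(B)), function(j) {
      f <- which(B[, j] == 1L)
      prio[prio %in% intersect(f, preferable)]
    })
    red <- gf2_reduce(B, row_priority = prio, column_prefer = prefer)
    r[k] <- red$rank
    tk <- sort(red$pivot_cols)
    tree[[k + 1L]] <- tk
    roles[[k + 1L]][tk] <- "tree"
    paired[[k]] <- sort(red$pivot_rows)
    roles[[k]][red$pivot_rows] <- "paired"
    # The pivot-row set is what matters for the homology bookkeeping (its
    # square submatrix against the tree columns is invertible); the Morse
    # matching additionally needs each pairing to run along a face
    # incidence. Invertibility forces an all-ones permutation of that
    # submatrix, i.e. a perfect face-matching between pivot rows and tree
    # columns always exists; realign the pivot assignment onto it.
    phi <- .face_align(B, red$pivot_cols, red$pivot_rows)
    partner_up[[k]][phi] <- red$pivot_cols
    partner_down[[k + 1L]][red$pivot_cols] <- phi
    prev_tree <- tk
  }
  critical <- lapply(seq_len(l + 1L), function(i) which(roles[[i]] == "critical"))
  rpad <- c(0L, r, 0L)
  betti <- vapply(0:l, function(k) m[k + 1L] - rpad[k + 1L] - rpad[k + 2L],
                  integer(1))
  if (!all(lengths(critical) == betti)) {
    stop("classification invariant violated: per-order critical counts ",
         "differ from the Betti numbers")
  }
  if (!is.null(start_nodes)) {
    sn <- sort(.label_index(K$labels, start_nodes))
    if (!identical(sn, critical[[1L]])) {
      stop("start_nodes must contain exactly one node per connected component")
    }
  }
  structure(list(roles = roles, tree = tree, paired = paired,
                 critical = critical, partner_up = partner_up,
                 partner_down = partner_down,
                 r = stats::setNames(r, seq_len(l)),
                 betti = stats::setNames(betti, 0:l)),
            class = "simplex_classification")
}

# Perfect matching between pivot columns and pivot rows along original face
# incidences (B[row, col] == 1). Pairs already face-aligned are kept;
# the rest are repaired by augmenting paths (Kuhn's algorithm), trying faces
# bottom-up. A perfect matching exists because the pivot submatrix is
# invertible over GF(2); failure therefore signals an internal error.
.face_align <- function(B, cols, rows) {
  nc <- length(cols)
  rowpos <- integer(nrow(B))
  rowpos[rows] <- seq_along(rows)
  adj <- lapply(cols, function(t) {
    f <- which(B[, t] == 1L)
    f <- f[f %in% rows]
    rev(rowpos[f]) # bottom-up
  })
  owner <- integer(length(rows)) # row position -> column position, 0 = free
  col_row <- integer(nc)
  for (i in seq_len(nc)) { # keep elimination pairs that are already faces
    rp <- rowpos[rows[i]]
    if (B[rows[i], cols[i]] == 1L && owner[rp] == 0L) {
      owner[rp] <- i
      col_row[i] <- rp
    }
  }
  augment <- function(ci, visited) {
    for (rp in adj[[ci]]) {
      if (visited[rp]) next
      visited[rp] <- TRUE
      o <- owner[rp]
      if (o == 0L) {
        owner[rp] <<- ci
        col_row[ci] <<- rp
        return(TRUE)
      }
      res <- augment(o, visited)
      if (res) {
        owner[rp] <<- ci
        col_row[ci] <<- rp
        return(TRUE)
      }
    }
    FALSE
  }
  for (ci in seq_len(nc)) {
    if (col_row[ci] != 0L) next
    if (!augment(ci, logical(length(rows)))) {
      stop("internal error: no face-aligned pairing for column ",
           colnames(B)[cols[ci]])
    }
  }
  rows[col_row]
}

#' @export
print.simplex_classification <- function(x, ...) {
  l <- length(x$roles) - 1L
  cat("simplex classification (orders 0..", l, ")\n", sep = "")
  for (k in 0:l) {
    cat("  order ", k, ": ",
        length(x$tree[[k + 1L]]), " tree, ",
        length(x$paired[[k + 1L]]), " paired, ",
        length(x$critical[[k + 1L]]), " critical\n", sep = "")
  }
  invisible(x)
}
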