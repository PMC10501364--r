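#' Row reduction over GF(2) with pivot bookkeeping
#'
#' Reduces a 0/1 matrix by XOR row operations, scanning columns greedily in
#' `column_order`. A column becomes a pivot if and only if it is linearly
#' independent (over GF(2)) of the pivot columns found before it; the pivot
#' row is the first still-unused row of `row_priority` that carries a 1 in
#' the current reduced column. The default `row_priority` is bottom-up
#' (last row first), which is the scan direction used to read spanning
#' trees off boundary matrices; with it, an edge column of a node-edge
#' matrix pivots at its larger endpoint.
#'
#' The rank and the pivot-column set depend only on `column_order`; the
#' pivot rows depend on `row_priority`.
#'
#' @param M integer 0/1 matrix.
#' @param column_order integer vector of column indices to scan, in order.
#'   Columns of `M` not listed are never pivot candidates but are carried
#'   through the row operations (used as right-hand sides by [gf2_solve()]).
#' @param row_priority integer permutation of row indices; earlier rows are
#'   preferred as pivots.
#' @param column_prefer optional list, parallel to `column_order`, of
#'   integer row vectors tried (in order) before `row_priority` when picking
#'   the pivot row of that column. Used to steer pairings onto faces.
#' @return an object of class `gf2_reduction`: a list with elements `rank`,
#'   `pivot_cols` and `pivot_rows` (parallel, in scan order), and `reduced`,
#'   the fully reduced matrix (pivot columns are unit vectors).
#' @examples
#' B <- matrix(c(1, 1, 0, 0, 1, 1, 1, 0, 1), 3, 3) # triangle node-edge matrix
#' gf2_reduce(B)$rank # 2: one edge is dependent, the cycle
#' @export
gf2_reduce <- function(M, column_order = seq_len(ncol(M)),
                       row_priority = rev(seq_len(nrow(M))),
                       column_prefer = NULL) {
  M <- .as_binary_matrix(M)
  stopifnot(length(column_order) == 0L || (min(column_order) >= 1L && max(column_order) <= ncol(M)))
  if (is.null(column_prefer)) {
    res <- .gf2_reduce_cpp(M, as.integer(column_order), as.integer(row_priority))
  } else {
    stopifnot(length(column_prefer) == length(column_order))
    res <- .gf2_reduce_prefer(M, as.integer(column_order),
                              as.integer(row_priority), column_prefer)
  }
  structure(list(rank = res$rank,
                 pivot_cols = as.integer(res$pivot_cols),
                 pivot_rows = as.integer(res$pivot_rows),
                 reduced = res$reduced),
            class = "gf2_reduction")
}

# R-level variant supporting per-column preferred pivot rows. Only used by
# classify_simplices(), where matrices are modest; the hot path without
# preferences stays in C++.
.gf2_reduce_prefer <- function(M, column_order, row_priority, column_prefer) {
  R <- M
  nr <- nrow(R)
  used <- logical(nr)
  piv_r <- integer(0)
  piv_c <- integer(0)
  for (t in seq_along(column_order)) {
    j <- column_order[[t]]
    col <- R[, j]
    cand <- c(column_prefer[[t]], row_priority)
    cand <- cand[!used[cand] & col[cand] == 1L]
    if (length(cand) == 0L) next
    p <- cand[[1L]]
    used[p] <- TRUE
    piv_r <- c(piv_r, p)
    piv_c <- c(piv_c, j)
    hit <- which(R[, j] == 1L)
    hit <- hit[hit != p]
    if (length(hit)) {
      R[hit, ] <- (R[hit, , drop = FALSE] + rep(R[p, ], each = length(hit))) %% 2L
    }
  }
  list(rank = length(piv_r), pivot_rows = piv_r, pivot_cols = piv_c, reduced = R)
}

#' @export
print.gf2_reduction <- function(x, ...) {
  cat("GF(2) reduction: rank", x$rank, "of a",
      nrow(x$reduced), "x", ncol(x$reduced), "matrix\n")
  cat("pivot columns:", paste(x$pivot_cols, collapse = " "), "\n")
  invisible(x)
}

#' Solve a GF(2) linear system with independent columns
#'
#' Returns the unique `x` with `A x = b (mod 2)`. The columns of `A` must be
#' linearly independent over GF(2) (as the columns of a spanning tree are),
#' and `b` must lie in their span; an inconsistent right-hand side signals
#' that a simplex believed critical actually bounds, and is an error.
#'
#' @param A integer 0/1 matrix with GF(2)-independent columns.
#' @param b 0/1 vector, or a matrix of right-hand-side columns.
#' @return a 0/1 integer vector (or matrix, one solution per column of `b`).
#' @export
gf2_solve <- function(A, b) {
  A <- .as_binary_matrix(A)
  bm <- if (is.matrix(b)) b else matrix(b, ncol = 1L)
  bm <- .as_binary_matrix(bm)
  stopifnot(nrow(bm) == nrow(A))
  if (ncol(A) == 0L) {
    if (any(bm != 0L)) stop("inconsistent GF(2) system: empty A, nonzero b")
    out <- matrix(integer(0), nrow = 0L, ncol = ncol(bm))
    return(if (is.matrix(b)) out else integer(0))
  }
  red <- gf2_reduce(cbind(A, bm), column_order = seq_len(ncol(A)))
  if (red$rank < ncol(A)) {
    stop("columns of A are not linearly independent over GF(2)")
  }
  non_pivot_rows <- setdiff(seq_len(nrow(A)), red$pivot_rows)
  rhs <- red$reduced[, ncol(A) + seq_len(ncol(bm)), drop = FALSE]
  if (length(non_pivot_rows) && any(rhs[non_pivot_rows, , drop = FALSE] != 0L)) {
    stop("inconsistent GF(2) system: right-hand side outside the column span")
  }
  x <- matrix(0L, nrow = ncol(A), ncol = ncol(bm))
  # pivot_cols[i] of A was pivoted at row pivot_rows[i]; the reduced rhs entry
  # at that row is the coefficient of that column.
  x[red$pivot_cols, ] <- rhs[red$pivot_rows, , drop = FALSE]
  if (is.matrix(b)) x else as.integer(x[, 1L])
}

.as_binary_matrix <- function(M) {
  if (!is.matrix(M)) stop("expected a matrix")
  storage.mode(M) <- "integer"
  if (length(M) && any(M != 0L & M != 1L)) stop("matrix entries must be 0 or 1")
  M
}
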