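# Exact rational arithmetic on num/den matrix pairs.
#
# Numerators and denominators are kept as integer-valued doubles, reduced by
# gcd after every operation; any intermediate exceeding 2^52 aborts rather
# than silently losing exactness. No tolerance parameter exists anywhere in
# these solvers: "zero" means numerator identically zero.

.RAT_LIMIT <- 2^52

.vgcd <- function(a, b) {
  a <- abs(a)
  b <- abs(b)
  while (any(b != 0)) {
    nz <- b != 0
    r <- a
    r[nz] <- a[nz] %% b[nz]
    a[nz] <- b[nz]
    b <- r
    b[!nz] <- 0
  }
  a[a == 0] <- 1
  a
}

.rat_canon <- function(num, den) {
  if (any(den == 0)) stop("rational with zero denominator")
  s <- ifelse(den < 0, -1, 1)
  num <- num * s
  den <- den * s
  g <- .vgcd(num, den)
  num <- num / g
  den <- den / g
  if (any(abs(num) > .RAT_LIMIT) || any(den > .RAT_LIMIT)) {
    stop("exact rational arithmetic overflow (entries exceed 2^52)")
  }
  list(num = num, den = den)
}

.rat_add <- function(an, ad, bn, bd) .rat_canon(an * bd + bn * ad, ad * bd)
.rat_mul <- function(an, ad, bn, bd) .rat_canon(an * bn, ad * bd)

#' Construct a rational matrix
#'
#' A thin exact-rational container: parallel numerator and denominator
#' matrices, always in lowest terms with positive denominators.
#'
#' @param num integer-valued numerator matrix.
#' @param den integer-valued denominator matrix (default all 1).
#' @return an object of class `rational_matrix` with elements `num`, `den`.
#' @export
rational_matrix <- function(num, den = NULL) {
  num <- as.matrix(num)
  if (is.null(den)) den <- matrix(1, nrow(num), ncol(num))
  den <- as.matrix(den)
  stopifnot(all(dim(num) == dim(den)),
            all(num == round(num)), all(den == round(den)))
  r <- .rat_canon(as.numeric(num), as.numeric(den))
  structure(list(num = matrix(r$num, nrow(num)), den = matrix(r$den, nrow(num))),
            class = "rational_matrix")
}

#' @export
print.rational_matrix <- function(x, ...) {
  s <- matrix(paste0(x$num, ifelse(x$den == 1, "", paste0("/", x$den))),
              nrow(x$num))
  print(s, quote = FALSE)
  invisible(x)
}

#' @export
as.matrix.rational_matrix <- function(x, ...) x$num / x$den

# Exact Gauss-Jordan elimination of the augmented rational system [G | H].
# Returns the reduced pair plus pivot bookkeeping.
.rat_eliminate <- function(num, den, pivot_limit = ncol(num)) {
  nr <- nrow(num)
  piv_rows <- integer(0)
  piv_cols <- integer(0)
  for (j in seq_len(pivot_limit)) {
    cand <- setdiff(which(num[, j] != 0), piv_rows)
    if (length(cand) == 0L) next
    p <- cand[[1L]]
    piv_rows <- c(piv_rows, p)
    piv_cols <- c(piv_cols, j)
    # scale pivot row to make entry (p, j) equal 1
    inv <- .rat_canon(den[p, j], num[p, j])
    row <- .rat_mul(num[p, ], den[p, ], inv$num, inv$den)
    num[p, ] <- row$num
    den[p, ] <- row$den
    for (i in seq_len(nr)) {
      if (i == p || num[i, j] == 0) next
      f <- list(num = -num[i, j], den = den[i, j])
      upd <- .rat_mul(row$num, row$den, f$num, f$den)
      res <- .rat_add(num[i, ], den[i, ], upd$num, upd$den)
      num[i, ] <- res$num
      den[i, ] <- res$den
    }
  }
  list(num = num, den = den, pivot_rows = piv_rows, pivot_cols = piv_cols,
       rank = length(piv_rows))
}

#' Exact rank of an integer matrix over the rationals
#'
#' @param M integer matrix.
#' @return integer rank, computed by exact rational elimination.
#' @export
rational_rank <- function(M) {
  M <- as.matrix(M)
  if (length(M) == 0L) return(0L)
  stopifnot(all(M == round(M)))
  num <- matrix(as.numeric(M), nrow(M))
  den <- matrix(1, nrow(M), ncol(M))
  .rat_eliminate(num, den)$rank
}

#' Exact rational solution of the normal equations
#'
#' Solves `(A' A) X = A' C` for `X` in exact rational arithmetic, i.e.
#' computes the least-squares coefficient matrix `X = (A'A)^{-1} A'C`. This
#' is the oriented form of the spanning-tree/critical-simplex equation: `A`
#' holds the signed boundary columns of the tree simplices and `C` those of
#' the critical simplices; the entrywise mod-2 image of `X` (see
#' [rational_mod2()]) recovers the GF(2) cavity solution while discarding
#' repeated-simplex artifacts of the oriented chain convention.
#'
#' @param A integer matrix whose columns are linearly independent over the
#'   rationals.
#' @param C integer matrix (same number of rows as `A`).
#' @return a [rational_matrix()] `X` with `ncol(A)` rows and `ncol(C)`
#'   columns, satisfying `(A'A) X = A'C` exactly.
#' @export
rational_normal_solve <- function(A, C) {
  A <- as.matrix(A)
  C <- as.matrix(C)
  stopifnot(all(A == round(A)), all(C == round(C)), nrow(A) == nrow(C))
  n <- ncol(A)
  if (n == 0L) {
    return(rational_matrix(matrix(0, 0L, ncol(C))))
  }
  G <- crossprod(A)            # A'A, integer
  H <- crossprod(A, C)         # A'C, integer
  num <- cbind(matrix(as.numeric(G), n), matrix(as.numeric(H), n))
  den <- matrix(1, n, n + ncol(C))
  el <- .rat_eliminate(num, den, pivot_limit = n)
  if (el$rank < n) {
    stop("A'A is singular: columns of A are rationally dependent")
  }
  X_num <- matrix(0, n, ncol(C))
  X_den <- matrix(1, n, ncol(C))
  rhs <- n + seq_len(ncol(C))
  X_num[el$pivot_cols, ] <- el$num[el$pivot_rows, rhs, drop = FALSE]
  X_den[el$pivot_cols, ] <- el$den[el$pivot_rows, rhs, drop = FALSE]
  rational_matrix(X_num, X_den)
}

#' Entrywise mod-2 image of a rational matrix
#'
#' Maps each entry p/q (in lowest terms, q odd) to `p mod 2`; q odd makes q
#' a unit mod 2, so the image is well defined. An even denominator has no
#' mod-2 image and is an error.
#'
#' @param X a [rational_matrix()].
#' @return integer 0/1 matrix.
#' @export
rational_mod2 <- function(X) {
  stopifnot(inherits(X, "rational_matrix"))
  if (any(X$den %% 2 == 0)) {
    stop("entry with even denominator has no mod-2 image")
  }
  matrix(as.integer(abs(X$num) %% 2), nrow(X$num))
}
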