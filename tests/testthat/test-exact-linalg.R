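test_that("gf2_reduce finds ranks and the printed torus pivot structure", {
  expect_equal(gf2_reduce(diag(5L))$rank, 5L)
  expect_equal(sort(gf2_reduce(diag(5L))$pivot_cols), 1:5)
  expect_equal(gf2_reduce(matrix(integer(0), 0, 0))$rank, 0L)

  # bottom-up scan of the torus node-edge matrix reads off the 1-tree
  K <- generate_fixture("torus9")
  red <- gf2_reduce(boundary_matrix(K, 1))
  expect_equal(red$rank, 8L)
  expect_equal(sort(simplex_keys(K, 1)[red$pivot_cols]),
               c("1,2", "1,3", "1,4", "1,5", "1,7", "1,9", "2,6", "2,8"))
  # pivot rows land at the larger endpoint, as in the printed table
  expect_equal(sort(red$pivot_rows), 2:9)
})

test_that("gf2_reduce rank matches exhaustive column-subset search", {
  set.seed(99)
  for (rep in 1:6) {
    nr <- sample(3:8, 1)
    nc <- sample(3:8, 1)
    M <- matrix(stats::rbinom(nr * nc, 1, 0.5), nr, nc)
    expect_equal(gf2_reduce(M)$rank, oracle_rank_subsets(M))
  }
})

test_that("rank and pivot columns are invariant under row priority", {
  set.seed(5)
  for (rep in 1:5) {
    M <- matrix(stats::rbinom(48, 1, 0.4), 6, 8)
    base <- gf2_reduce(M)
    for (perm in list(1:6, 6:1, sample(6))) {
      alt <- gf2_reduce(M, row_priority = perm)
      expect_equal(alt$rank, base$rank)
      expect_equal(alt$pivot_cols, base$pivot_cols)
    }
  }
})

test_that("gf2_solve reproduces the printed torus tree coefficients", {
  expect_equal(gf2_solve(diag(4L), c(1L, 0L, 1L, 1L)), c(1L, 0L, 1L, 1L))

  K <- generate_fixture("torus9")
  B <- boundary_matrix(K, 1)
  keys <- simplex_keys(K, 1)
  tree <- c("1,2", "1,3", "1,4", "1,5", "1,7", "1,9", "2,6", "2,8")
  A <- B[, match(tree, keys)]
  X <- gf2_solve(A, B[, match(c("2,3", "4,7"), keys)])
  expect_equal(unname(X),
               rbind(c(1L, 0L), c(1L, 0L), c(0L, 1L), c(0L, 0L),
                     c(0L, 1L), c(0L, 0L), c(0L, 0L), c(0L, 0L)))
})

test_that("gf2_solve agrees with exhaustive enumeration and round-trips", {
  set.seed(17)
  for (rep in 1:4) {
    n <- sample(4:8, 1)
    repeat { # random full-column-rank A
      A <- matrix(stats::rbinom(12 * n, 1, 0.5), 12, n)
      if (gf2_reduce(A)$rank == n) break
    }
    x <- stats::rbinom(n, 1, 0.5)
    b <- as.integer((A %*% x) %% 2L)
    expect_equal(gf2_solve(A, b), as.integer(x))
    sols <- oracle_gf2_solutions(A, b)
    expect_length(sols, 1L)
    expect_equal(sols[[1L]], as.integer(x))
  }
  # inconsistent right-hand side signals a misclassified simplex
  A <- rbind(c(1L, 0L), c(0L, 1L), c(0L, 0L))
  expect_error(gf2_solve(A, c(0L, 0L, 1L)), "inconsistent")
  expect_error(gf2_solve(cbind(c(1L, 1L), c(1L, 1L)), c(1L, 1L)),
               "independent")
})

test_that("rational_normal_solve is exact and consistent with GF(2)", {
  C <- matrix(c(2, -3, 5, 7), 2, 2)
  X <- rational_normal_solve(diag(2), C)
  expect_equal(as.matrix(X), C)

  set.seed(23)
  for (rep in 1:4) {
    n <- sample(3:4, 1)
    repeat {
      A <- matrix(sample(-1:1, 8 * n, replace = TRUE), 8, n)
      if (qr(A)$rank == n) break
    }
    C <- matrix(sample(-1:1, 8 * 2, replace = TRUE), 8, 2)
    X <- rational_normal_solve(A, C)
    # defining identity A'A X = A'C, checked exactly entry by entry after
    # clearing each column's denominators (sizes chosen so every product
    # stays far below 2^53 and double arithmetic is exact)
    G <- crossprod(A)
    lcm2 <- function(a, b) {
      g <- a
      h <- b
      while (h) {
        t <- g %% h
        g <- h
        h <- t
      }
      a / g * b
    }
    scale <- apply(X$den, 2, function(d) Reduce(lcm2, d))
    expect_lt(max(abs(scale)) * max(abs(X$num)), 2^50)
    num_scaled <- sweep(X$num, 2, scale, "*") / X$den
    expect_true(all(num_scaled == round(num_scaled)))
    lhs <- G %*% num_scaled
    rhs <- sweep(crossprod(A, C), 2, scale, "*")
    expect_true(all(lhs == rhs))
  }

  expect_error(rational_normal_solve(cbind(c(1, 1), c(2, 2)), cbind(c(1, 0))),
               "singular")

  # mod-2 image of the oriented torus solve equals the GF(2) solve
  K <- generate_fixture("torus9")
  cls <- classify_simplices(K)
  Bo <- boundary_matrix(K, 1, oriented = TRUE)
  Xo <- rational_normal_solve(Bo[, cls$tree[[2]]], Bo[, cls$critical[[2]]])
  Bu <- boundary_matrix(K, 1)
  Xu <- gf2_solve(Bu[, cls$tree[[2]]], Bu[, cls$critical[[2]]])
  expect_equal(rational_mod2(Xo), unname(Xu))
})

test_that("rational helpers reduce fractions and reject even denominators", {
  X <- rational_matrix(matrix(c(2, 3), 1), matrix(c(4, 9), 1))
  expect_equal(X$num, matrix(c(1, 1), 1))
  expect_equal(X$den, matrix(c(2, 3), 1))
  expect_error(rational_mod2(X), "even denominator")
  expect_equal(rational_mod2(rational_matrix(matrix(c(5, -3, 2), 1),
                                             matrix(c(3, 1, 1), 1))),
               matrix(c(1L, 1L, 0L), 1))
  expect_equal(rational_rank(diag(4)), 4L)
  expect_equal(rational_rank(matrix(c(1, 2, 2, 4), 2)), 1L)
})
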