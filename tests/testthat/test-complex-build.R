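test_that("clique complexes of small graphs have the expected simplices", {
  tri <- matrix(1, 3, 3) - diag(3)
  expect_equal(simplex_counts(build_clique_complex(tri, 2)), c(3L, 3L, 1L))

  K4 <- build_clique_complex(matrix(1, 4, 4) - diag(4), 3)
  expect_equal(simplex_counts(K4), c(4L, 6L, 4L, 1L))
  expect_equal(homology_profile(K4)$euler, 1L) # a solid simplex is contractible

  # max_order truncates enumeration
  expect_equal(simplex_counts(build_clique_complex(matrix(1, 4, 4) - diag(4), 1)),
               c(4L, 6L))
})

test_that("clique enumeration agrees with exhaustive subset search", {
  set.seed(421)
  for (rep in 1:3) {
    n <- 12L
    adj <- matrix(0L, n, n)
    adj[upper.tri(adj)] <- stats::rbinom(n * (n - 1L) / 2L, 1L, 0.4)
    adj <- adj + t(adj)
    K <- build_clique_complex(adj, max_order = 3)
    want <- oracle_clique_counts(adj, 3L)
    got <- simplex_counts(K)
    expect_equal(got, want[seq_along(got)])
    expect_true(all(want[-seq_along(got)] == 0L))
  }
})

test_that("malformed graph input is rejected", {
  bad <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_error(build_clique_complex(bad, 1), "symmetric")
  loop <- diag(2)
  expect_error(build_clique_complex(loop, 1), "self-loop")
  expect_error(build_clique_complex(rbind(c("a", "a")), 1), "self-loop")
})

test_that("explicit complexes are face closures without clique completion", {
  K <- generate_fixture("torus9")
  expect_equal(simplex_counts(K), c(9L, 27L, 18L))
  # unfilled triangles of the 1-skeleton: (1,2,3) is a 3-cycle but no 2-simplex
  expect_false("1,2,3" %in% simplex_keys(K, 2))
  expect_true(all(c("1,2", "2,3", "1,3") %in% simplex_keys(K, 1)))

  expect_equal(simplex_counts(build_explicit(list(c(1, 2, 3)))), c(3L, 3L, 1L))

  # closure is idempotent: rebuilding from all simplices reproduces K
  all_simplices <- do.call(c, lapply(0:2, function(k) {
    m <- simplices(K, k)
    lapply(seq_len(nrow(m)), function(i) m[i, ])
  }))
  expect_equal(build_explicit(all_simplices)$simplices, K$simplices)

  # empty input is a valid empty network
  expect_equal(build_explicit(list())$max_order, -1L)
  # duplicated input simplices collapse
  expect_equal(simplex_counts(build_explicit(list(c(1, 2), c(2, 1)))),
               c(2L, 1L))
  expect_error(build_explicit(list(c(1, 1, 2))), "repeated vertex")
})

test_that("Rips complexes are clique complexes of the neighborhood graph", {
  pts <- matrix(c(0, 0, 1, 0, 0.5, sqrt(3) / 2), ncol = 2, byrow = TRUE)
  expect_equal(simplex_counts(build_rips(pts, 0, 2)), 3L) # nodes only
  K <- build_rips(pts, 1.1, 2)
  expect_equal(simplex_counts(K), c(3L, 3L, 1L))
  expect_equal(K$birth[[1]], c(0, 0, 0))
  expect_equal(K$birth[[2]], rep(1, 3), tolerance = 1e-12)
  expect_equal(K$birth[[3]], 1, tolerance = 1e-12)

  set.seed(77)
  pts <- matrix(stats::rnorm(40), ncol = 2)
  th <- 0.9
  D <- as.matrix(dist(pts))
  adj <- (D <= th) * 1
  diag(adj) <- 0
  rownames(adj) <- colnames(adj) <- seq_len(nrow(pts))
  KR <- build_rips(pts, th, 3)
  KC <- build_clique_complex(adj, 3)
  expect_equal(KR$simplices, KC$simplices)
  # birth value of a simplex is its largest pairwise distance
  for (k in 1:KR$max_order) {
    m <- KR$simplices[[k + 1L]]
    for (i in head(seq_len(nrow(m)), 5L)) {
      expect_equal(KR$birth[[k + 1L]][i], max(D[m[i, ], m[i, ]]))
    }
  }
  expect_error(build_rips(matrix(c(1, NA), 1), 1, 1), "numeric")
})

test_that("boundary matrices follow the (-1)^p sign rule and square to zero", {
  K1 <- build_explicit(list(c(1, 2)))
  expect_equal(unname(boundary_matrix(K1, 1)[, 1]), c(1L, 1L))
  expect_equal(unname(boundary_matrix(K1, 1, oriented = TRUE)[, 1]),
               c(-1L, 1L))

  KT <- build_explicit(list(c(1, 2, 3)))
  B2 <- boundary_matrix(KT, 2, oriented = TRUE)
  expect_equal(B2[c("2,3", "1,3", "1,2"), 1], c("2,3" = 1L, "1,3" = -1L,
                                                "1,2" = 1L))

  for (K in list(generate_fixture("torus9"), generate_fixture("klein_bottle"),
                 rand_network(11), rand_network(12))) {
    for (k in seq_len(K$max_order)) {
      B <- boundary_matrix(K, k)
      expect_equal(sum(B), (k + 1L) * ncol(B)) # k+1 faces per column
      if (k >= 2L) {
        expect_true(all(boundary_matrix(K, k - 1L, oriented = TRUE) %*%
                          boundary_matrix(K, k, oriented = TRUE) == 0))
        expect_true(all((boundary_matrix(K, k - 1L) %*% B) %% 2L == 0L))
      }
    }
  }
  expect_error(boundary_matrix(generate_fixture("torus9"), 3), "order")
})

test_that("homology profiles satisfy the rank and Euler identities", {
  hp <- torus9_profile()
  expect_equal(unname(hp$r), c(8L, 17L))
  expect_equal(unname(hp$betti), c(1L, 2L, 1L))
  expect_equal(hp$euler, 0L)

  expect_equal(unname(homology_profile(build_explicit(list(1)))$betti), 1L)

  KO <- generate_fixture("octahedron")
  expect_equal(unname(homology_profile(KO)$betti), c(1L, 0L, 1L))
  expect_equal(unname(homology_profile(KO)$betti), oracle_betti(KO))

  for (seed in 31:34) {
    K <- rand_network(seed)
    hp <- homology_profile(K)
    expect_equal(unname(hp$betti), oracle_betti(K))
    expect_equal(sum((-1L)^(0:K$max_order) * hp$m),
                 sum((-1L)^(0:K$max_order) * hp$betti)) # chi both ways
  }
})

test_that("disconnected networks count components through beta_0", {
  K <- build_explicit(list(c(1, 2), c(3, 4), 5))
  expect_equal(unname(homology_profile(K)$betti), c(3L, 0L))
})
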