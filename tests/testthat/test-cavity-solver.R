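test_that("the torus cavity equation yields the printed representatives", {
  K <- generate_fixture("torus9")
  b1 <- solve_cavities_gf2(K, 1)
  expect_equal(b1$members, list(c("1,2", "1,3", "2,3"),
                                c("1,4", "1,7", "4,7")))
  b2 <- solve_cavities_gf2(K, 2)
  expect_length(b2$supports, 1L)
  expect_equal(b2$lengths, 18L) # the whole triangulation
  expect_true(cavity_independence(b1, K))
  expect_true(cavity_independence(b2, K))
})

test_that("simple fixtures have the forced cavities", {
  KH <- generate_fixture("hollow_triangle")
  expect_equal(solve_cavities_gf2(KH, 1)$members,
               list(c("1,2", "1,3", "2,3")))
  KO <- generate_fixture("octahedron")
  bo <- solve_cavities_gf2(KO, 2)
  # brute force: ker(B_2) is one-dimensional, so the 8-face support is forced
  B2 <- boundary_matrix(KO, 2)
  kernel <- oracle_gf2_solutions(B2, integer(nrow(B2)))
  nonzero <- Filter(function(x) any(x == 1L), kernel)
  expect_length(nonzero, 1L)
  expect_equal(which(nonzero[[1L]] == 1L), bo$supports[[1L]])
  # a complex with no cavities at an order yields an empty basis
  expect_length(solve_cavities_gf2(KO, 1)$supports, 0L)
  expect_equal(length_distribution(solve_cavities_gf2(KO, 1))$counts,
               integer(0))
})

test_that("every solved cavity is a mod-2 cycle forming an independent basis", {
  fixtures <- list(generate_fixture("torus9"), generate_fixture("octahedron"),
                   generate_fixture("klein_bottle"), rand_network(301),
                   rand_network(302), rand_network(303))
  for (K in fixtures) {
    cls <- classify_simplices(K)
    for (k in seq_len(K$max_order)) {
      b <- solve_cavities_gf2(K, k, classification = cls)
      expect_length(b$supports, unname(cls$betti[k + 1L]))
      for (s in b$supports) {
        expect_cycle(K, k, s)
        expect_gte(length(s), k + 2L) # no k-cycle shorter than a simplex boundary
      }
      expect_true(cavity_independence(b, K))
    }
  }
})

test_that("the oriented rational solver agrees with GF(2) mod 2", {
  fixtures <- list(generate_fixture("torus9"), generate_fixture("octahedron"),
                   generate_fixture("hollow_triangle"), rand_network(311),
                   rand_network(312))
  for (K in fixtures) {
    for (k in seq_len(K$max_order)) {
      a <- solve_cavities_gf2(K, k)
      o <- solve_cavities_oriented(K, k)
      expect_equal(o$supports, a$supports)
    }
  }
  # 2-torsion: the Klein bottle's 2-cavity exists over GF(2) only, so the
  # rational solve has no well-defined mod-2 image there
  KB <- generate_fixture("klein_bottle")
  expect_equal(solve_cavities_oriented(KB, 1)$supports,
               solve_cavities_gf2(KB, 1)$supports)
  expect_error(solve_cavities_oriented(KB, 2), "denominator")
})

test_that("length distributions count representatives by length", {
  K <- generate_fixture("torus9")
  ld <- length_distribution(solve_cavities_gf2(K, 1))
  expect_equal(ld$counts, c("3" = 2L))
  expect_equal(ld$total_length, 6L)
})

test_that("reduce_basis shortens an inflated cycle back to the original", {
  # octahedron sphere with a tetrahedron glued on face (1,2,3)
  KO <- generate_fixture("octahedron")
  faces <- lapply(seq_len(8L), function(i) simplices(KO, 2)[i, ])
  KT <- build_explicit(c(faces, list(c(1, 2, 7), c(1, 3, 7), c(2, 3, 7),
                                     c(1, 2, 3, 7))))
  b <- solve_cavities_gf2(KT, 2)
  expect_length(b$supports, 1L)
  orig <- b$supports[[1L]]
  # inflate: add the boundary of the glued 3-simplex (1,2,3,7)
  B3 <- boundary_matrix(KT, 3)
  tet_boundary <- which(B3[, 1L] == 1L)
  inflated <- sort(setdiff(union(orig, tet_boundary),
                           intersect(orig, tet_boundary)))
  expect_gt(length(inflated), length(orig))
  expect_cycle(KT, 2, inflated)
  bad <- structure(b, class = "cavity_basis")
  bad$supports <- list(inflated)
  bad$members <- list(simplex_keys(KT, 2)[inflated])
  bad$lengths <- length(inflated)
  bad$total_length <- length(inflated)
  rec <- reduce_basis(bad, KT)
  expect_equal(rec$supports[[1L]], orig)
})

test_that("reduce_basis never lengthens and preserves basis rank", {
  for (seed in 321:324) {
    K <- rand_network(seed)
    cls <- classify_simplices(K)
    for (k in seq_len(K$max_order)) {
      b <- solve_cavities_gf2(K, k, classification = cls)
      if (length(b$supports) == 0L) next
      rb <- reduce_basis(b, K)
      expect_lte(rb$total_length, b$total_length)
      expect_true(cavity_independence(rb, K))
      for (s in rb$supports) expect_cycle(K, k, s)
    }
  }
})

test_that("exhaustive 1-cavity search finds minimum-length bases", {
  K5 <- build_explicit(list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 5)))
  expect_equal(optimal_1_cavities(K5)$lengths, 5L)

  K <- generate_fixture("torus9")
  ob <- optimal_1_cavities(K)
  expect_equal(ob$lengths, c(3L, 3L))
  expect_true(cavity_independence(ob, K))
  expect_true(ob$complete)

  # two hollow squares joined by a bridge edge
  Ksq <- build_explicit(list(c(1, 2), c(2, 3), c(3, 4), c(1, 4), c(4, 5),
                             c(5, 6), c(6, 7), c(7, 8), c(5, 8)))
  osq <- optimal_1_cavities(Ksq)
  expect_equal(osq$lengths, c(4L, 4L))
  for (s in osq$supports) expect_cycle(Ksq, 1, s)

  # an exhausted budget returns a partial basis with a warning
  expect_warning(ob2 <- optimal_1_cavities(K, budget = 3),
                 "budget")
  expect_false(ob2$complete)
})

test_that("Hodge nullities equal Betti numbers except under torsion", {
  K <- generate_fixture("torus9")
  expect_equal(vapply(0:2, function(k) hodge_betti(K, k), integer(1)),
               c(1L, 2L, 1L))
  KO <- generate_fixture("octahedron")
  expect_equal(vapply(0:2, function(k) hodge_betti(KO, k), integer(1)),
               c(1L, 0L, 1L))
  expect_equal(hodge_betti(build_explicit(list(c(1, 2, 3))), 0), 1L)
  # Klein bottle: GF(2) sees (1,2,1), the rational Laplacian (1,1,0)
  KB <- generate_fixture("klein_bottle")
  expect_equal(unname(homology_profile(KB)$betti), c(1L, 2L, 1L))
  expect_equal(vapply(0:2, function(k) hodge_betti(KB, k), integer(1)),
               c(1L, 1L, 0L))
  # rank decomposition agrees with direct elimination of L_k when feasible
  B1 <- boundary_matrix(KO, 1, oriented = TRUE)
  B2 <- boundary_matrix(KO, 2, oriented = TRUE)
  L1 <- crossprod(B1) + tcrossprod(B2)
  expect_equal(hodge_betti(KO, 1), as.integer(nrow(L1) - rational_rank(L1)))
})
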