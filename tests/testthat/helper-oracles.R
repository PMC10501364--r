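# Independent oracles used to check the package's linear algebra and
# homology against brute force. These deliberately share no code with the
# implementation: plain top-down row echelon, exhaustive subset search,
# and exhaustive GF(2) vector enumeration.

# top-down row-echelon rank over GF(2), no bit packing, no pivot rules
oracle_gf2_rank <- function(M) {
  M <- as.matrix(M) %% 2L
  r <- 0L
  for (j in seq_len(ncol(M))) {
    piv <- which(M[, j] == 1L)
    piv <- piv[piv > r]
    if (length(piv) == 0L) next
    r <- r + 1L
    if (piv[1L] != r) M[c(r, piv[1L]), ] <- M[c(piv[1L], r), ]
    for (i in seq_len(nrow(M))) {
      if (i != r && M[i, j] == 1L) M[i, ] <- (M[i, ] + M[r, ]) %% 2L
    }
  }
  r
}

# rank = size of the largest column subset with no vanishing XOR combination
oracle_rank_subsets <- function(M) {
  nc <- ncol(M)
  best <- 0L
  for (mask in seq_len(2L^nc) - 1L) {
    S <- which(bitwAnd(mask, 2L^(seq_len(nc) - 1L)) > 0L)
    if (length(S) <= best) next
    ok <- TRUE
    for (sub in seq_len(2L^length(S) - 1L)) {
      combo <- S[bitwAnd(sub, 2L^(seq_along(S) - 1L)) > 0L]
      v <- rowSums(M[, combo, drop = FALSE]) %% 2L
      if (all(v == 0L)) {
        ok <- FALSE
        break
      }
    }
    if (ok) best <- length(S)
  }
  best
}

# brute-force GF(2) Betti numbers: dim ker - dim im via the oracle rank
oracle_betti <- function(K) {
  l <- K$max_order
  m <- simplex_counts(K)
  r <- integer(l + 2L)
  if (l >= 1L) {
    for (k in seq_len(l)) r[k + 1L] <- oracle_gf2_rank(boundary_matrix(K, k))
  }
  vapply(0:l, function(k) {
    dim_ker <- m[k + 1L] - r[k + 1L]
    dim_ker - r[k + 2L]
  }, integer(1))
}

# all x in {0,1}^n with A x = b, by exhaustive enumeration
oracle_gf2_solutions <- function(A, b) {
  n <- ncol(A)
  out <- list()
  for (mask in seq_len(2L^n) - 1L) {
    x <- as.integer(bitwAnd(mask, 2L^(seq_len(n) - 1L)) > 0L)
    if (all((A %*% x) %% 2L == b %% 2L)) out[[length(out) + 1L]] <- x
  }
  out
}

# exhaustive clique enumeration over all vertex subsets (n <= 12)
oracle_clique_counts <- function(adj, max_order) {
  n <- nrow(adj)
  counts <- integer(max_order + 1L)
  for (size in seq_len(max_order + 1L)) {
    cliques <- 0L
    for (S in utils::combn(n, size, simplify = FALSE)) {
      connected <- size == 1L ||
        all(vapply(utils::combn(S, 2L, simplify = FALSE),
                   function(p) adj[p[1L], p[2L]] == 1L, logical(1)))
      if (connected) cliques <- cliques + 1L
    }
    counts[size] <- cliques
  }
  counts
}

# seeded small random clique complexes for property tests
rand_network <- function(seed, n = NULL, p = NULL, max_order = 3L) {
  set.seed(seed)
  if (is.null(n)) n <- sample(6:10, 1L)
  if (is.null(p)) p <- stats::runif(1L, 0.35, 0.6)
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- stats::rbinom(n * (n - 1L) / 2L, 1L, p)
  adj <- adj + t(adj)
  build_clique_complex(adj, max_order = max_order)
}

expect_cycle <- function(K, k, support) {
  B <- boundary_matrix(K, k)
  x <- integer(ncol(B))
  x[support] <- 1L
  expect_true(all((B %*% x) %% 2L == 0L))
}

torus9_profile <- function() homology_profile(generate_fixture("torus9"))
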