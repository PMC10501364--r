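#' Assign optimal discrete Morse values from a simplex classification
#'
#' Builds a discrete Morse function whose critical simplices are exactly
#' the cavity-generating simplices of the classification, so their
#' per-order counts equal the Betti numbers (the theoretical minimum).
#' Values are assigned in phases:
#' \enumerate{
#'   \item the start node of a component receives the next value (0 for the
#'     first component);
#'   \item breadth-first traversal of the 1-order spanning tree: each newly
#'     reached node shares the next value with the tree edge that reached
#'     it (incident tree edges are tried in lexicographic order);
#'   \item critical edges, in lexicographic order, one value each;
#'   \item for each higher order k: tree k-simplices in lexicographic order
#'     with a deferral queue --- a (paired face, tree simplex) pair is
#'     emitted, sharing the next value, only once all other faces of the
#'     k-simplex already carry values; then the critical k-simplices.
#' }
#' For a connected network the maximum value is
#' `n = r_1 + beta_1 + r_2 + beta_2 + ... + r_l + beta_l`.
#'
#' @param K a `simplicial_network`.
#' @param classification a [classify_simplices()] result; computed if
#'   missing.
#' @param start_nodes optional start node labels (one per component),
#'   forwarded to [classify_simplices()] when `classification` is missing.
#' @return an object of class `morse_function`: list with `values` (per
#'   order, numeric vectors aligned with the simplex lists), `pairing_up`
#'   (paired k-simplex -> partner (k+1)-simplex index), `critical` (index
#'   vectors per order), and `n` (the maximum value).
#' @examples
#' K <- generate_fixture("torus9")
#' f <- assign_morse(K)
#' f$n # 28
#' @export
assign_morse <- function(K, classification = NULL, start_nodes = NULL) {
  stopifnot(inherits(K, "simplicial_network"))
  if (is.null(classification)) {
    classification <- classify_simplices(K, start_nodes = start_nodes)
  }
  cls <- classification
  l <- K$max_order
  if (l < 0L) {
    return(structure(list(values = list(), pairing_up = list(),
                          critical = list(), n = -1),
                     class = "morse_function"))
  }
  values <- lapply(K$counts, function(n) rep(NA_real_, n))
  pairing_up <- lapply(K$counts, function(n) rep(NA_integer_, n))
  counter <- -1

  # phase 0/1: per component, root then breadth-first tree traversal
  roots <- cls$critical[[1L]]
  tree_edges <- if (l >= 1L) cls$tree[[2L]] else integer(0)
  edge_mat <- if (l >= 1L) K$simplices[[2L]] else matrix(0L, 0L, 2L)
  incident <- vector("list", length(K$labels))
  for (e in tree_edges) { # ascending e keeps incidence lists lexicographic
    incident[[edge_mat[e, 1L]]] <- c(incident[[edge_mat[e, 1L]]], e)
    incident[[edge_mat[e, 2L]]] <- c(incident[[edge_mat[e, 2L]]], e)
  }
  edge_done <- rep(FALSE, nrow(edge_mat))
  for (root in sort(roots)) {
    counter <- counter + 1
    values[[1L]][root] <- counter
    queue <- root
    while (length(queue)) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      for (e in incident[[u]]) {
        if (edge_done[e]) next
        w <- setdiff(edge_mat[e, ], u)
        if (!is.na(values[[1L]][w])) next
        edge_done[e] <- TRUE
        counter <- counter + 1
        values[[1L]][w] <- counter
        values[[2L]][e] <- counter
        pairing_up[[1L]][w] <- e
        queue <- c(queue, w)
      }
    }
  }

  if (l >= 1L) {
    for (e in cls$critical[[2L]]) {
      counter <- counter + 1
      values[[2L]][e] <- counter
    }
  }

  for (k in seq_len(l)[-1L]) {
    B <- boundary_matrix(K, k)
    pending <- cls$tree[[k + 1L]] # ascending = lexicographic
    while (length(pending)) {
      emitted <- logical(length(pending))
      for (i in seq_along(pending)) {
        t <- pending[[i]]
        faces <- which(B[, t] == 1L)
        partner <- cls$partner_down[[k + 1L]][t]
        others <- setdiff(faces, partner)
        if (all(!is.na(values[[k]][others]))) {
          counter <- counter + 1
          values[[k]][partner] <- counter
          values[[k + 1L]][t] <- counter
          pairing_up[[k]][partner] <- t
          emitted[i] <- TRUE
        }
      }
      if (!any(emitted)) {
        stop("Morse assignment deadlock: no emittable pair among ",
             paste(simplex_keys(K, k)[cls$partner_down[[k + 1L]][pending]],
                   collapse = "; "))
      }
      pending <- pending[!emitted]
    }
    for (cr in cls$critical[[k + 1L]]) {
      counter <- counter + 1
      values[[k + 1L]][cr] <- counter
    }
  }

  structure(list(values = values, pairing_up = pairing_up,
                 critical = cls$critical, n = counter),
            class = "morse_function")
}

#' @export
print.morse_function <- function(x, ...) {
  cat("discrete Morse function with values 0..", x$n, "\n", sep = "")
  cat("critical simplices per order:",
      paste(lengths(x$critical), collapse = " "), "\n")
  invisible(x)
}

# Accept either a morse_function or a plain per-order list of value vectors.
.morse_values <- function(K, f) {
  v <- if (inherits(f, "morse_function")) f$values else f
  if (!is.list(v) || length(v) != K$max_order + 1L ||
      !all(lengths(v) == K$counts) || anyNA(unlist(v))) {
    stop("f must assign one finite value to every simplex of K ",
         "(a per-order list of value vectors)")
  }
  lapply(v, as.numeric)
}

# For each adjacent order pair, the matrix of "wrong-way" incidences:
# entry (i, j) is 1 iff face i of coface j has f(face) >= f(coface).
.wrongway <- function(K, vals, k) {
  B <- boundary_matrix(K, k)
  B * outer(vals[[k]], vals[[k + 1L]], ">=")
}

#' Validate a discrete Morse function
#'
#' Checks Forman's conditions for every simplex: at most one coface of one
#' order higher with a value not above its own (`#U <= 1`), and at most one
#' face of one order lower with a value not below its own (`#V <= 1`).
#'
#' @param K a `simplicial_network`.
#' @param f a [assign_morse()] result or a per-order list of value vectors.
#' @return list with `valid` (logical) and `violations`, a data frame of
#'   offending simplices with their `#U` and `#V` counts.
#' @export
is_discrete_morse <- function(K, f) {
  vals <- .morse_values(K, f)
  uv <- .uv_counts(K, vals)
  bad <- uv[uv$n_up > 1L | uv$n_down > 1L, , drop = FALSE]
  list(valid = nrow(bad) == 0L, violations = bad)
}

.uv_counts <- function(K, vals) {
  l <- K$max_order
  out <- list()
  up <- lapply(K$counts, function(n) rep(0L, n))
  down <- lapply(K$counts, function(n) rep(0L, n))
  if (l >= 1L) {
    for (k in seq_len(l)) {
      W <- .wrongway(K, vals, k)
      up[[k]] <- as.integer(rowSums(W))
      down[[k + 1L]] <- as.integer(colSums(W))
    }
  }
  do.call(rbind, lapply(0:l, function(k) {
    data.frame(order = k,
               key = simplex_keys(K, k),
               value = vals[[k + 1L]],
               n_up = up[[k + 1L]],
               n_down = down[[k + 1L]],
               stringsAsFactors = FALSE)
  }))
}

#' Critical simplices of a discrete Morse function
#'
#' A simplex is critical iff it has no coface of one order higher with a
#' value not above its own and no face of one order lower with a value not
#' below its own (`#U = 0` and `#V = 0`).
#'
#' @inheritParams is_discrete_morse
#' @return list with `sets` (per order, the critical simplex keys),
#'   `indices` (per order, their positions) and `counts` (the numbers
#'   `c_k`).
#' @export
critical_simplices <- function(K, f) {
  vals <- .morse_values(K, f)
  uv <- .uv_counts(K, vals)
  crit <- uv[uv$n_up == 0L & uv$n_down == 0L, , drop = FALSE]
  l <- K$max_order
  sets <- lapply(0:l, function(k) crit$key[crit$order == k])
  indices <- lapply(0:l, function(k) {
    which(simplex_keys(K, k) %in% sets[[k + 1L]])
  })
  list(sets = sets, indices = indices,
       counts = stats::setNames(vapply(sets, length, integer(1)), 0:l))
}

#' Build the nested filtration induced by a Morse function
#'
#' Simplices are grouped by ascending value; the union of the first i
#' groups is the subnetwork K_i, and validity requires every such prefix to
#' be face-closed, i.e. no simplex may carry a smaller value than one of
#' its faces.
#'
#' @inheritParams is_discrete_morse
#' @return an object of class `filtration`: list with the `network`, the
#'   per-order `values`, the sorted distinct `levels`, `groups` (a data
#'   frame with columns `value`, `order`, `index`, `key`), and `n` (the
#'   largest value).
#' @export
build_filtration <- function(K, f) {
  vals <- .morse_values(K, f)
  if (K$max_order >= 1L) {
    for (k in seq_len(K$max_order)) {
      B <- boundary_matrix(K, k)
      late <- B * outer(vals[[k]], vals[[k + 1L]], ">")
      if (any(late == 1L)) {
        j <- which(colSums(late) > 0L)[[1L]]
        stop("invalid filtration: simplex ", colnames(B)[j],
             " appears before its face ",
             rownames(B)[which(late[, j] == 1L)[[1L]]])
      }
    }
  }
  groups <- do.call(rbind, lapply(0:K$max_order, function(k) {
    data.frame(value = vals[[k + 1L]], order = k,
               index = seq_len(K$counts[k + 1L]),
               key = simplex_keys(K, k), stringsAsFactors = FALSE)
  }))
  groups <- groups[order(groups$value, groups$order, groups$index), ,
                   drop = FALSE]
  rownames(groups) <- NULL
  structure(list(network = K, values = vals,
                 levels = sort(unique(groups$value)), groups = groups,
                 n = max(c(-1, groups$value))),
            class = "filtration")
}

#' @export
print.filtration <- function(x, ...) {
  cat("filtration with", length(x$levels), "levels, K_0 ... K_", x$n,
      "\n", sep = "")
  invisible(x)
}

#' Subnetwork of a filtration at a given value
#'
#' @param filtration a [build_filtration()] result.
#' @param v Morse value; the returned network holds all simplices with
#'   value at most `v`.
#' @return a `simplicial_network`.
#' @export
filtration_prefix <- function(filtration, v) {
  stopifnot(inherits(filtration, "filtration"))
  K <- filtration$network
  g <- filtration$groups
  g <- g[g$value <= v, , drop = FALSE]
  keep <- lapply(0:K$max_order, function(k) {
    K$simplices[[k + 1L]][g$index[g$order == k], , drop = FALSE]
  })
  keep <- keep[vapply(keep, nrow, integer(1)) > 0L]
  used <- sort(unique(unlist(lapply(keep, as.vector))))
  relabel <- match(seq_along(K$labels), used)
  keep <- lapply(keep, function(m) matrix(relabel[m], nrow = nrow(m)))
  .new_network(keep, K$labels[used])
}

#' Persistence barcode of a filtration
#'
#' Standard GF(2) boundary-column reduction in filtration order (ties are
#' broken lower order first, then lexicographically, so faces always
#' precede cofaces). Finite bars record the birth and death Morse values of
#' homology classes; zero-length bars are suppressed; classes that never
#' die are reported as persistent bars with `death = Inf`. For the
#' generated optimal assignment every non-critical pair cancels
#' immediately, so the barcode holds exactly `beta_k` persistent bars per
#' dimension and no finite bars.
#'
#' @param filtration a [build_filtration()] result.
#' @return an object of class `persistence_barcode`: a data frame with
#'   columns `dimension`, `birth`, `death`.
#' @export
persistence <- function(filtration) {
  stopifnot(inherits(filtration, "filtration"))
  K <- filtration$network
  g <- filtration$groups
  N <- nrow(g)
  pos <- lapply(K$counts, function(n) integer(n))
  for (p in seq_len(N)) pos[[g$order[p] + 1L]][g$index[p]] <- p
  faces_of <- vector("list", K$max_order + 1L)
  if (K$max_order >= 1L) {
    for (k in seq_len(K$max_order)) {
      B <- boundary_matrix(K, k)
      faces_of[[k + 1L]] <- lapply(seq_len(ncol(B)),
                                   function(j) which(B[, j] == 1L))
    }
  }
  cols <- vector("list", N)
  low_owner <- integer(N)
  killed <- logical(N)
  pair_of <- integer(N)
  for (p in seq_len(N)) {
    k <- g$order[p]
    col <- if (k == 0L) integer(0) else {
      sort(pos[[k]][faces_of[[k + 1L]][[g$index[p]]]])
    }
    while (length(col)) {
      lo <- col[[length(col)]]
      o <- low_owner[lo]
      if (o == 0L) break
      merged <- c(col, cols[[o]])
      merged <- sort(merged)
      col <- merged[!(duplicated(merged) | duplicated(merged, fromLast = TRUE))]
    }
    if (length(col)) {
      lo <- col[[length(col)]]
      low_owner[lo] <- p
      cols[[p]] <- col
      killed[lo] <- TRUE
      pair_of[p] <- lo
    }
  }
  positive <- vapply(seq_len(N), function(p) is.null(cols[[p]]), logical(1))
  bars <- list()
  for (p in which(pair_of > 0L)) {
    lo <- pair_of[p]
    if (g$value[lo] < g$value[p]) {
      bars[[length(bars) + 1L]] <- data.frame(dimension = g$order[lo],
                                              birth = g$value[lo],
                                              death = g$value[p])
    }
  }
  for (p in which(positive & !killed)) {
    bars[[length(bars) + 1L]] <- data.frame(dimension = g$order[p],
                                            birth = g$value[p],
                                            death = Inf)
  }
  out <- if (length(bars)) do.call(rbind, bars) else {
    data.frame(dimension = integer(0), birth = numeric(0), death = numeric(0))
  }
  out <- out[order(out$dimension, out$birth, out$death), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("persistence_barcode", "data.frame")
  out
}
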