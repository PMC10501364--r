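#' Read a network input file
#'
#' Supported dialects:
#' \describe{
#'   \item{edge_list}{TSV with two columns of node labels; lines starting
#'     with `#` are ignored.}
#'   \item{adjacency}{CSV of 0/1 entries, square; an optional header row
#'     and first label column are detected.}
#'   \item{simplex_list}{one simplex per line, comma-separated labels; or
#'     a JSON list of lists when the file extension is `.json`.}
#'   \item{point_cloud}{CSV of numeric coordinates, one point per row.}
#' }
#'
#' @param path input file.
#' @param format one of the dialects above.
#' @return the raw input structure: a two-column label matrix
#'   (`edge_list`), a 0/1 matrix (`adjacency`), a list of label vectors
#'   (`simplex_list`), or a numeric matrix (`point_cloud`). Feed it to
#'   [build_clique_complex()], [build_explicit()] or [build_rips()].
#' @export
read_network <- function(path, format = c("edge_list", "adjacency",
                                          "simplex_list", "point_cloud")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format,
         edge_list = .read_edge_list(path),
         adjacency = .read_adjacency(path),
         simplex_list = .read_simplex_list(path),
         point_cloud = .read_point_cloud(path))
}

.content_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(text = lines[keep], lineno = which(keep))
}

.read_edge_list <- function(path) {
  lc <- .content_lines(path)
  parts <- strsplit(lc$text, "\t| +")
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad)) {
    stop("malformed edge list ", path, ": expected two fields on line ",
         paste(lc$lineno[bad], collapse = ", "))
  }
  matrix(unlist(parts), ncol = 2L, byrow = TRUE)
}

.read_adjacency <- function(path) {
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  has_header <- !all(vapply(raw[1L, ], function(x)
    !is.na(suppressWarnings(as.numeric(x))), logical(1)))
  if (has_header) {
    raw <- utils::read.csv(path, header = TRUE, row.names = 1L,
                           check.names = FALSE)
    M <- as.matrix(raw)
  } else {
    M <- as.matrix(raw)
    dimnames(M) <- NULL
  }
  storage.mode(M) <- "numeric"
  if (anyNA(M)) stop("malformed adjacency matrix in ", path)
  if (nrow(M) != ncol(M)) stop("adjacency matrix in ", path, " is not square")
  M
}

.read_simplex_list <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    return(lapply(x, function(s) unlist(s, use.names = FALSE)))
  }
  lc <- .content_lines(path)
  out <- strsplit(trimws(lc$text), "\\s*,\\s*")
  bad <- which(vapply(out, function(s) any(s == ""), logical(1)))
  if (length(bad)) {
    stop("malformed simplex list ", path, ": empty label on line ",
         paste(lc$lineno[bad], collapse = ", "))
  }
  out
}

.read_point_cloud <- function(path) {
  M <- as.matrix(utils::read.csv(path, header = FALSE))
  storage.mode(M) <- "numeric"
  if (anyNA(M)) stop("malformed point cloud in ", path,
                     ": non-numeric coordinate")
  dimnames(M) <- NULL
  M
}

.maximal_simplices <- function(K) {
  l <- K$max_order
  if (l < 0L) return(list())
  out <- list()
  covered <- lapply(K$counts, function(n) rep(FALSE, n))
  for (k in l:0) {
    if (k >= 1L) {
      B <- boundary_matrix(K, k)
    }
    for (i in seq_len(K$counts[k + 1L])) {
      if (covered[[k + 1L]][i]) next
      out[[length(out) + 1L]] <- simplices(K, k)[i, ]
    }
    if (k >= 1L) {
      has_any <- rowSums(B) > 0L # faces of anything are covered
      covered[[k]] <- covered[[k]] | has_any
    }
  }
  out
}

#' Write a network as a simplex-list file
#'
#' Emits the maximal simplices (one per line, comma-separated labels);
#' [build_explicit()] on the re-read file reproduces the network exactly.
#'
#' @param K a `simplicial_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network <- function(K, path) {
  stopifnot(inherits(K, "simplicial_network"))
  lines <- vapply(.maximal_simplices(K), paste, character(1), collapse = ",")
  writeLines(lines, path)
  invisible(path)
}

#' Write a persistence barcode as TSV
#'
#' Columns `dimension`, `birth`, `death`; persistent bars print `inf`.
#'
#' @param bars a [persistence()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_barcode <- function(bars, path) {
  stopifnot(inherits(bars, "persistence_barcode"))
  df <- as.data.frame(bars)
  df$death <- ifelse(is.infinite(df$death), "inf",
                     format(df$death, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write cavity bases as JSON
#'
#' @param bases a `cavity_basis` or a list of them (one per order).
#' @param K the network the bases were computed on (for the independence
#'   check recorded in the output).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cavities <- function(bases, K, path) {
  if (inherits(bases, "cavity_basis")) bases <- list(bases)
  payload <- lapply(bases, function(b) {
    list(order = b$order,
         representatives = lapply(seq_along(b$supports), function(i) {
           m <- simplices(K, b$order)[b$supports[[i]], , drop = FALSE]
           lapply(seq_len(nrow(m)), function(r) m[r, ])
         }),
         lengths = b$lengths,
         total_length = b$total_length,
         independent = cavity_independence(b, K),
         complete = isTRUE(b$complete))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
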