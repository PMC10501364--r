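#' Full analysis report of a simplicial network
#'
#' Bundles the simplex counts, spanning-tree ranks, Betti numbers, Euler
#' characteristic, per-order critical counts and filtration length, with
#' optional barcode and cavity summaries. All quantities are mutually
#' consistent by construction: `beta_k = m_k - r_k - r_{k+1}`, the
#' alternating sums of `m`, of the critical counts and of `beta` all equal
#' `chi`, and `n = r_1 + beta_1 + ... + r_l + beta_l` on a connected
#' network.
#'
#' @param K a `simplicial_network`.
#' @param cavities logical; solve and include all-order cavity bases.
#' @param barcode logical; include the (noise-free) barcode of the
#'   generated optimal Morse filtration.
#' @return an object of class `analysis_report` (a list ready for JSON
#'   serialisation).
#' @export
analysis_report <- function(K, cavities = FALSE, barcode = FALSE) {
  stopifnot(inherits(K, "simplicial_network"))
  cls <- classify_simplices(K)
  f <- assign_morse(K, cls)
  rep <- list(m = unname(K$counts),
              r = unname(cls$r),
              betti = unname(cls$betti),
              euler = sum((-1L)^(0:K$max_order) * K$counts),
              critical_counts = unname(lengths(cls$critical)),
              filtration_length = f$n)
  if (barcode) {
    bars <- persistence(build_filtration(K, f))
    df <- as.data.frame(bars)
    df$death[is.infinite(df$death)] <- NA
    rep$barcode <- df
  }
  if (cavities) {
    rep$cavities <- lapply(seq_len(max(0L, K$max_order)), function(k) {
      b <- solve_cavities_gf2(K, k, classification = cls)
      list(order = k, count = length(b$supports),
           lengths = unname(b$lengths), total_length = b$total_length,
           representatives = b$members)
    })
  }
  structure(rep, class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("m_k:            ", paste(x$m, collapse = " "), "\n")
  cat("r_k:            ", paste(x$r, collapse = " "), "\n")
  cat("beta_k:         ", paste(x$betti, collapse = " "), "\n")
  cat("chi:            ", x$euler, "\n")
  cat("critical counts:", paste(x$critical_counts, collapse = " "), "\n")
  cat("filtration n:   ", x$filtration_length, "\n")
  invisible(x)
}
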