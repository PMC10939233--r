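#' Per-cell Fisher's exact test for PLA product enrichment
#'
#' For every cell and every product i:j a 2x2 contingency table is formed
#' from the cell's PLA counts:
#' \preformatted{
#'                  probe B = j            probe B != j
#'   probe A = i    X[i,j]                 sum_{l != j} X[i,l]
#'   probe A != i   sum_{k != i} X[k,j]    sum_{k != i, l != j} X[k,l]
#' }
#' and a one-sided (enrichment) exact test asks whether `X[i,j]` is larger
#' than expected from the margins.  P-values are Benjamini-Hochberg
#' corrected across products within each cell; a product is called in a
#' cell when its adjusted p-value is below `alpha`.  Products with
#' `X[i,j] = 0` or degenerate margins get p = 1.
#'
#' At the population level the fraction of positive cells per product is
#' reported; a product is summarized as detected when that fraction
#' exceeds `min_fraction`.  The fraction threshold is a reporting
#' convention, not part of the test: under the null the per-cell call rate
#' is bounded by `alpha` per cell, so well-expressed complexes separate
#' clearly from it.
#'
#' @param x cells x products PLA count matrix ("i:j" column names).
#' @param alpha per-cell BH level.
#' @param min_fraction population-level reporting threshold on the
#'   fraction of positive cells.
#' @return object of class `fisher_result`: matrices `p_adj` and `calls`
#'   (cells x products), the per-product `fraction_positive`, and the
#'   population-level `detected` flags.
#' @export
fisher_detect <- function(x, alpha = 0.05, min_fraction = 0.1) {
  x <- as.matrix(x)
  pi <- panel_index(x)
  row_m <- x %*% pi$memb_a
  col_m <- x %*% pi$memb_b
  tot <- rowSums(x)
  P <- ncol(x)
  praw <- matrix(1, nrow(x), P, dimnames = dimnames(x))
  for (p in seq_len(P)) {
    a <- x[, p]
    m <- row_m[, pi$a[p]]          # white balls: probe A = i
    k <- col_m[, pi$b[p]]          # draws: probe B = j
    ok <- a > 0 & tot > 0 & m > 0 & k > 0
    # one-sided enrichment p: upper hypergeometric tail at the observed cell
    praw[ok, p] <- phyper(a[ok] - 1, m[ok], tot[ok] - m[ok], k[ok],
                          lower.tail = FALSE)
  }
  p_adj <- t(apply(praw, 1L, p.adjust, method = "BH"))
  dimnames(p_adj) <- dimnames(x)
  calls <- p_adj < alpha
  frac <- colMeans(calls)
  structure(list(p_adj = p_adj, calls = calls,
                 fraction_positive = frac,
                 detected = frac > min_fraction,
                 alpha = alpha, min_fraction = min_fraction),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat("Per-cell Fisher enrichment test:", nrow(x$calls), "cells x",
      ncol(x$calls), "products\n")
  top <- sort(x$fraction_positive, decreasing = TRUE)
  top <- top[top > 0]
  if (length(top))
    cat("  positive-cell fractions > 0:\n    ",
        paste(sprintf("%s=%.2f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}
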