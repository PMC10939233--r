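#' Settings for the iterative complex predictor
#'
#' @param max_iterations iteration cap.
#' @param tolerance convergence threshold on the maximum change, across
#'   products, of the mean predicted count between iterations (UMIs).
#' @param sym_weight symmetry weight: if product i:j passes the population
#'   t-test but j:i fails, `Y[j,i]` is set to `sym_weight * Y[i,j]`.
#' @param alpha Benjamini-Hochberg level of the per-iteration population
#'   test.
#' @param mean_threshold alternative hypothesis of the one-sided, one-sample
#'   t-test: mean predicted count greater than this value (UMIs).
#' @param init optional cells x products matrix of initial complex counts
#'   (all zeros by default); the ensemble method passes the LR output here.
#' @return list of class `iterative_settings`.
#' @export
iterative_settings <- function(max_iterations = 100L, tolerance = 0.01,
                               sym_weight = 1, alpha = 0.05,
                               mean_threshold = 1, init = NULL) {
  stopifnot(tolerance > 0, alpha > 0, alpha < 1, max_iterations >= 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, sym_weight = sym_weight,
                 alpha = alpha, mean_threshold = mean_threshold,
                 init = init),
            class = "iterative_settings")
}

# One-sided one-sample t-test p-values, H1: mean > mu, per column.
# Zero-variance columns collapse to a point mass: p = 0 if the common value
# exceeds mu, else 1.
col_ttest_greater <- function(y, mu) {
  nc <- nrow(y)
  m <- colMeans(y)
  s <- apply(y, 2L, sd)
  p <- rep(1, ncol(y))
  degen <- s == 0 | is.na(s)
  p[degen] <- ifelse(m[degen] > mu, 0, 1)
  ok <- !degen
  if (any(ok)) {
    tstat <- (m[ok] - mu) / (s[ok] / sqrt(nc))
    p[ok] <- pt(tstat, df = nc - 1L, lower.tail = FALSE)
  }
  setNames(p, colnames(y))
}

#' Iterative prediction of protein-complex counts
#'
#' Starting from the initial complex matrix (zeros by default), each
#' iteration updates, per cell,
#' \deqn{Y_{i,j} \leftarrow X_{i,j} -
#'   \frac{(\sum_l X_{i,l} - \sum_l Y_{i,l})
#'         (\sum_k X_{k,j} - \sum_k Y_{k,j})}
#'        {\sum\sum X - \sum\sum Y}}
#' i.e. subtracts the random-ligation count expected from the margins of
#' the counts not yet attributed to complexes.  After every update a
#' one-sided one-sample t-test across cells asks whether the mean of each
#' product's predicted count exceeds `mean_threshold`; products whose
#' Benjamini-Hochberg-adjusted p-value exceeds `alpha` are zeroed
#' population-wide.  A symmetry rule then fills `Y[j,i]` from a passing
#' partner `Y[i,j]`.  Iteration stops when the mean predicted count of
#' every product changes by less than `tolerance`.
#'
#' Negative per-cell values are retained during iteration (they inform the
#' population test) and clipped to zero only in the returned matrix.
#' Cells whose residual total `sum(X) - sum(Y)` is not positive (possible
#' when the initialization overshoots the observed counts) skip the
#' update -- their values are carried forward -- and the run is flagged.
#'
#' @param x cells x products PLA count matrix ("i:j" column names; at least
#'   2 cells).
#' @param settings an [iterative_settings()] list.
#' @return a `complex_prediction` with the per-cell complex count matrix
#'   `y`, per-product detection flags and BH-adjusted p-values (final
#'   iteration), the iteration count and convergence status.
#' @examples
#' x <- matrix(rep(c(10, 0, 0, 10), each = 3), 3,
#'             dimnames = list(NULL, c("P1:P1", "P1:P2", "P2:P1", "P2:P2")))
#' iterative_predict(x)
#' @export
iterative_predict <- function(x, settings = iterative_settings()) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("iterative_predict needs at least 2 cells")
  pi <- panel_index(x)
  P <- ncol(x)
  flags <- character(0)
  y <- settings$init
  if (is.null(y)) {
    y <- matrix(0, nrow(x), P, dimnames = dimnames(x))
  } else {
    y <- as.matrix(y)
    if (!all(dim(y) == dim(x))) stop("init matrix dimensions must match x")
    y <- y[, colnames(x), drop = FALSE]
  }
  row_x <- x %*% pi$memb_a
  col_x <- x %*% pi$memb_b
  tot_x <- rowSums(x)
  mu <- settings$mean_threshold
  sym_partner <- match(paste(pi$proteins[pi$b], pi$proteins[pi$a],
                             sep = ":"), colnames(x))
  converged <- FALSE
  p_adj <- setNames(rep(NA_real_, P), colnames(x))
  keep <- rep(FALSE, P)
  it <- 0L
  for (it in seq_len(settings$max_iterations)) {
    row_y <- y %*% pi$memb_a
    col_y <- y %*% pi$memb_b
    denom <- tot_x - rowSums(y)
    bad <- denom <= 0
    if (any(bad) && !("nonpositive_denominator" %in% flags))
      flags <- c(flags, "nonpositive_denominator")
    denom[bad] <- 1
    # residual margins are counts not yet attributed to complexes; an
    # overshooting initialization can push them negative, which would let
    # two negative margins multiply into runaway positive updates -- they
    # are clamped at zero instead
    res_a <- pmax(row_x - row_y, 0)
    res_b <- pmax(col_x - col_y, 0)
    y_new <- x - (res_a[, pi$a, drop = FALSE] *
                    res_b[, pi$b, drop = FALSE]) / denom
    y_new[bad, ] <- y[bad, ]     # no update where the residual total is gone
    p_adj <- p.adjust(col_ttest_greater(y_new, mu), method = "BH")
    keep <- p_adj <= settings$alpha
    y_new[, !keep] <- 0
    # symmetry: a detected i:j implies a nonzero j:i even if j:i failed
    fill <- which(keep & !keep[sym_partner] & sym_partner != seq_len(P))
    for (p in fill)
      y_new[, sym_partner[p]] <- settings$sym_weight * y_new[, p]
    delta <- max(abs(colMeans(y_new) - colMeans(y)))
    y <- y_new
    if (delta < settings$tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged) flags <- c(flags, "max_iterations_reached")
  detected <- keep
  detected[sym_partner[keep & sym_partner != seq_len(P)]] <- TRUE
  names(detected) <- colnames(x)
  y[y < 0] <- 0
  y[, !detected] <- 0
  new_complex_prediction(y = y, detected = detected, p_adj = p_adj,
                         method = "iterative", iterations = it,
                         converged = converged, flags = flags)
}
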