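#' Settings for the linear-regression (LR) complex predictor
#'
#' @param beta_cutoff alternative hypothesis of the one-sided intercept
#'   test, `beta0 > beta_cutoff`; 1 for simulated data (10 is appropriate
#'   for experimental data).
#' @param alpha Benjamini-Hochberg level across products.
#' @param interaction_scale divisor applied to the interaction term
#'   `A'_i * B'_j` when it is much larger than the response, for numerical
#'   conditioning only; the fitted slope and the predicted counts are
#'   invariant to it.
#' @param max_dropped_frac products for which more than this fraction of
#'   cells has `A'_i * B'_j = 0` (undefined weight) are flagged unreliable.
#' @return list of class `lr_settings`.
#' @export
lr_settings <- function(beta_cutoff = 1, alpha = 0.05,
                        interaction_scale = 1e6, max_dropped_frac = 0.5) {
  stopifnot(beta_cutoff >= 0, alpha > 0, alpha < 1, interaction_scale > 0)
  structure(list(beta_cutoff = beta_cutoff, alpha = alpha,
                 interaction_scale = interaction_scale,
                 max_dropped_frac = max_dropped_frac),
            class = "lr_settings")
}

#' Linear-regression prediction of protein-complex counts
#'
#' For each PLA product i:j the observed count is regressed across cells on
#' the product of the measured non-proximal ("free oligo") probe counts,
#' `X[i,j] ~ beta0 + beta1 * A'_i * B'_j`, by weighted least squares with
#' per-cell weight `1 / (A'_i * B'_j)` (the counts are strongly
#' heteroscedastic).  The slope estimates the proximity-noise rate -- with
#' perfect non-proximal proxies `beta1 = d^2 / (4 R^2)` -- and a one-sided
#' t-test on the intercept (`beta0 > beta_cutoff`, BH-corrected at `alpha`
#' across products) decides detection.  Detected products get the per-cell
#' complex count `Y = max(0, X - beta1 * A'B')`; all others are zero.
#'
#' Cells with `A'B' = 0` are dropped from that product's fit (their weight
#' is undefined); a product is skipped (undetected, flagged) when fewer
#' than 3 cells remain.  A negative fitted slope is permitted but flagged.
#' When the interaction term is more than 1000x the median response it is
#' rescaled by `interaction_scale` before fitting, which leaves `beta1`
#' (reported on the original scale) and `Y` unchanged.
#'
#' @param x cells x products PLA count matrix ("i:j" column names).
#' @param nonproximal cells x 2n matrix of free-oligo counts, with columns
#'   `"<p>:free_oligo_B"` (non-proximal probe A of p) and
#'   `"free_oligo_A:<p>"` (non-proximal probe B), as written by
#'   [simulate_population()].
#' @param settings an [lr_settings()] list.
#' @return a `complex_prediction`; `coefficients` holds the per-product
#'   `beta0`, `beta1`, adjusted p and per-product flags.
#' @export
lr_predict <- function(x, nonproximal, settings = lr_settings()) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("lr_predict needs at least 3 cells")
  pi <- panel_index(x)
  np <- split_nonproximal(nonproximal, pi$proteins)
  if (nrow(np$a) != nrow(x))
    stop("non-proximal matrix must cover the same cells as x")
  P <- ncol(x)
  beta0 <- beta1 <- pval <- rep(NA_real_, P)
  prod_flag <- character(P)
  y <- matrix(0, nrow(x), P, dimnames = dimnames(x))
  for (p in seq_len(P)) {
    inter <- np$a[, pi$a[p]] * np$b[, pi$b[p]]
    okc <- inter > 0
    if (sum(okc) < 3L) {
      prod_flag[p] <- "skipped_no_nonproximal"
      pval[p] <- 1
      next
    }
    if (mean(!okc) > settings$max_dropped_frac)
      prod_flag[p] <- "unreliable_many_zero_weights"
    xi <- inter[okc]
    yi <- x[okc, p]
    scale <- if (median(xi) > 1e3 * max(median(yi), 1))
      settings$interaction_scale else 1
    xs <- xi / scale
    w <- 1 / xi
    if (var(xs) == 0) {
      # degenerate design: no information about the slope
      beta1[p] <- 0
      beta0[p] <- sum(w * yi) / sum(w)
      resid <- yi - beta0[p]
      se0 <- sqrt(sum(w * resid^2) / (length(yi) - 1L) / sum(w))
      dfree <- length(yi) - 1L
      prod_flag[p] <- paste0(prod_flag[p], "+constant_interaction")
    } else {
      fit <- lm(yi ~ xs, weights = w)
      cf <- coef(fit)
      beta0[p] <- cf[1L]
      beta1[p] <- cf[2L] / scale
      # an exact fit gives se 0; the p-value collapses to 0/1 below
      se0 <- suppressWarnings(sqrt(vcov(fit)[1L, 1L]))
      dfree <- df.residual(fit)
    }
    if (!is.na(beta1[p]) && beta1[p] < 0)
      prod_flag[p] <- paste0(prod_flag[p], "+negative_slope")
    if (is.na(se0) || se0 == 0) {
      pval[p] <- ifelse(beta0[p] > settings$beta_cutoff, 0, 1)
    } else {
      tstat <- (beta0[p] - settings$beta_cutoff) / se0
      pval[p] <- pt(tstat, df = dfree, lower.tail = FALSE)
    }
  }
  p_adj <- setNames(p.adjust(pval, method = "BH"), colnames(x))
  detected <- p_adj <= settings$alpha
  detected[is.na(detected)] <- FALSE
  for (p in which(detected)) {
    inter <- np$a[, pi$a[p]] * np$b[, pi$b[p]]
    y[, p] <- pmax(0, x[, p] - beta1[p] * inter)
  }
  coefs <- data.frame(product = colnames(x), beta0 = beta0, beta1 = beta1,
                      p_adj = p_adj, detected = detected,
                      flag = sub("^\\+", "", prod_flag),
                      row.names = NULL)
  new_complex_prediction(y = y, detected = detected, p_adj = p_adj,
                         method = "lr", coefficients = coefs,
                         flags = unique(prod_flag[nzchar(prod_flag)]))
}

#' Ensemble prediction: LR-initialized iterative method
#'
#' Runs [lr_predict()] and uses its per-cell complex count matrix as the
#' initial values of [iterative_predict()].  Starting the iteration near
#' the LR estimate keeps it out of the spurious fixed points that an
#' all-zero initialization can fall into, which is what makes the ensemble
#' robust across both high and low signal-to-noise regimes.
#'
#' @param x cells x products PLA count matrix.
#' @param nonproximal free-oligo count matrix, as in [lr_predict()].
#' @param lr_settings settings for the LR stage.
#' @param it_settings settings for the iterative stage (its `init` is
#'   replaced by the LR output).
#' @return a `complex_prediction` with `method = "ensemble"`; the LR
#'   stage's coefficients are attached.
#' @export
ensemble_predict <- function(x, nonproximal,
                             lr_settings = proxsim::lr_settings(),
                             it_settings = iterative_settings()) {
  lr <- lr_predict(x, nonproximal, lr_settings)
  it_settings$init <- lr$y
  out <- iterative_predict(x, it_settings)
  out$method <- "ensemble"
  out$coefficients <- lr$coefficients
  out$flags <- unique(c(out$flags, lr$flags))
  out
}
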