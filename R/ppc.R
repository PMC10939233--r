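#' Posterior-predictive check statistics
#'
#' Compares observed and model-replicated count matrices feature by
#' feature with two statistics: the coefficient of variation (how well the
#' mean-variance relationship is preserved) and the scaled Mann-Whitney U
#' statistic `U / (n1 * n2)` between the observed and replicated samples
#' (0.5 means the two samples are indistinguishable in rank; ties get
#' mid-ranks).
#'
#' @param observed cells x features count matrix.
#' @param replicated cells x features matrix replicated from the model;
#'   must share the feature panel (cell counts may differ).
#' @return data.frame per feature with `cv_observed`, `cv_replicated`,
#'   `u_scaled` and a `flag` for zero-mean features; column means are in
#'   `attr(, "summary")`.
#' @export
ppc_statistics <- function(observed, replicated) {
  observed <- as.matrix(observed)
  replicated <- as.matrix(replicated)
  if (ncol(observed) != ncol(replicated))
    stop("observed and replicated must share the feature panel")
  if (!is.null(colnames(observed)) && !is.null(colnames(replicated))) {
    if (!setequal(colnames(observed), colnames(replicated)))
      stop("observed and replicated must share the feature panel")
    replicated <- replicated[, colnames(observed), drop = FALSE]
  }
  cv <- function(v) if (mean(v) == 0) NA_real_ else sd(v) / mean(v)
  n1 <- nrow(observed); n2 <- nrow(replicated)
  res <- lapply(seq_len(ncol(observed)), function(p) {
    o <- observed[, p]; r <- replicated[, p]
    rk <- rank(c(o, r))                      # mid-ranks for ties
    u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
    data.frame(feature = colnames(observed)[p] %||% p,
               cv_observed = cv(o), cv_replicated = cv(r),
               u_scaled = u / (n1 * n2),
               flag = if (mean(o) == 0 || mean(r) == 0)
                 "zero_mean" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "summary") <- c(mean_cv_observed =
                              mean(out$cv_observed, na.rm = TRUE),
                            mean_cv_replicated =
                              mean(out$cv_replicated, na.rm = TRUE),
                            mean_u_scaled = mean(out$u_scaled))
  out
}

#' Fit the negative binomial dispersion per feature
#'
#' Maximum-likelihood fit of the NB dispersion `n_NB` (the `size`
#' parameter) across cells for each feature, with the NB mean fixed at its
#' MLE, the sample mean.  Under-dispersed features (sample variance at or
#' below the mean, the Poisson limit) have an unbounded likelihood in
#' `n_NB` and are reported censored at `cap`; constant features are
#' degenerate.
#'
#' @param x count vector, or cells x features count matrix.
#' @param cap upper bound at which the dispersion estimate is censored.
#' @return data.frame per feature: `mean`, `n_nb` and a `flag`
#'   (`"censored"`, `"degenerate"` or empty).
#' @examples
#' set.seed(1)
#' fit_nb_dispersion(rnbinom(1000, size = 1.5, mu = 50))
#' @export
fit_nb_dispersion <- function(x, cap = 1e4) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  x <- as.matrix(x)
  if (nrow(x) < 20L) stop("need at least 20 observations per feature")
  res <- lapply(seq_len(ncol(x)), function(p) {
    v <- x[, p]
    m <- mean(v)
    feature <- colnames(x)[p] %||% p
    if (var(v) == 0)
      return(data.frame(feature = feature, mean = m, n_nb = NA_real_,
                        flag = "degenerate", stringsAsFactors = FALSE))
    if (var(v) <= m)
      return(data.frame(feature = feature, mean = m, n_nb = cap,
                        flag = "censored", stringsAsFactors = FALSE))
    ll <- function(log_size)
      sum(dnbinom(v, size = exp(log_size), mu = m, log = TRUE))
    opt <- optimize(ll, c(log(1e-3), log(cap)), maximum = TRUE)
    est <- exp(opt$maximum)
    # near-Poisson data: likelihood is flat in the dispersion out to the cap
    flat <- ll(log(cap)) >= opt$objective - 0.01
    if (est >= 0.95 * cap || flat) {
      est <- cap
      flag <- "censored"
    } else flag <- ""
    data.frame(feature = feature, mean = m, n_nb = est, flag = flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
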