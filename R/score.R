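#' Weights of the prediction score
#'
#' The score is `w1 * sum(Pearson) - w2 * sum(Mean_deviation) -
#' w3 * sum(FP_rate)`.  The defaults (0.5, 0.4, 0.1) weight single-cell
#' correlation highest, bulk mean accuracy next, and the false-positive
#' rate least.
#'
#' @param w1,w2,w3 non-negative weights.
#' @return list of class `score_weights`.
#' @export
score_weights <- function(w1 = 0.5, w2 = 0.4, w3 = 0.1) {
  stopifnot(w1 >= 0, w2 >= 0, w3 >= 0)
  structure(list(w1 = w1, w2 = w2, w3 = w3), class = "score_weights")
}

#' Score a complex prediction against simulation ground truth
#'
#' Three components are computed over the shared cells x products panel:
#' \itemize{
#'   \item `sum_pearson`: for every true complex (true mean > 0), the
#'     Pearson correlation across cells between true and predicted counts,
#'     summed; a zero-variance prediction contributes 0 and is flagged.
#'   \item `sum_mean_deviation`: for every true complex,
#'     `|mean_pred - mean_true| / mean_true`, summed.
#'   \item `sum_fp_rate`: for every product whose true count is zero in
#'     all cells, the fraction of cells with a positive predicted count,
#'     summed.
#' }
#' and combined as `w1 * sum_pearson - w2 * sum_mean_deviation -
#' w3 * sum_fp_rate`.  A perfect prediction of k complexes scores
#' `0.5 * k` under the default weights.
#'
#' @param truth cells x products matrix of true complex counts.
#' @param predicted cells x products matrix of predicted counts, or a
#'   `complex_prediction`.
#' @param weights a [score_weights()] list.
#' @return object of class `score_report` with the components, the score
#'   and the number of true complexes.
#' @export
prediction_score <- function(truth, predicted, weights = score_weights()) {
  if (inherits(predicted, "complex_prediction")) predicted <- predicted$y
  truth <- as.matrix(truth)
  predicted <- as.matrix(predicted)
  if (!all(dim(truth) == dim(predicted)))
    stop("truth and predicted must have identical dimensions")
  if (!is.null(colnames(truth)) && !is.null(colnames(predicted))) {
    if (!setequal(colnames(truth), colnames(predicted)))
      stop("truth and predicted must share the product panel")
    predicted <- predicted[, colnames(truth), drop = FALSE]
  }
  true_mean <- colMeans(truth)
  is_true <- true_mean > 0
  flags <- character(0)
  sum_pearson <- 0
  sum_dev <- 0
  for (p in which(is_true)) {
    if (sd(predicted[, p]) == 0 || sd(truth[, p]) == 0) {
      flags <- c(flags, paste0("zero_variance:",
                               colnames(truth)[p] %||% p))
    } else {
      sum_pearson <- sum_pearson + cor(truth[, p], predicted[, p])
    }
    sum_dev <- sum_dev +
      abs(mean(predicted[, p]) - true_mean[[p]]) / true_mean[[p]]
  }
  fp <- 0
  for (p in which(!is_true)) fp <- fp + mean(predicted[, p] > 0)
  score <- weights$w1 * sum_pearson - weights$w2 * sum_dev -
    weights$w3 * fp
  structure(list(sum_pearson = sum_pearson,
                 sum_mean_deviation = sum_dev,
                 sum_fp_rate = fp,
                 score = score,
                 n_true_complexes = sum(is_true),
                 weights = weights, flags = flags),
            class = "score_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf(paste0("Prediction score: %.3f  (sum Pearson %.3f, ",
                     "sum mean deviation %.3f, sum FP rate %.3f; ",
                     "%d true complexes)\n"),
              x$score, x$sum_pearson, x$sum_mean_deviation, x$sum_fp_rate,
              x$n_true_complexes))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "),
                           "\n")
  invisible(x)
}
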