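#' Run the simulate-predict-score benchmark
#'
#' For every configuration, simulates a population, runs each requested
#' predictor, and scores it against the simulated ground truth with
#' [prediction_score()].  A predictor failure on one run is recorded (NA
#' score) rather than fatal.
#'
#' @param configs list of [sim_config()] objects, e.g. from
#'   [generate_scenarios()].
#' @param methods subset of `c("iterative", "lr", "ensemble")`.
#' @param weights a [score_weights()] list.
#' @param lr_settings,it_settings predictor settings.
#' @return data.frame with one row per configuration x method: scenario
#'   annotation (when present), the three score components and the score.
#' @export
run_benchmark <- function(configs,
                          methods = c("iterative", "lr", "ensemble"),
                          weights = score_weights(),
                          lr_settings = proxsim::lr_settings(),
                          it_settings = iterative_settings()) {
  stopifnot(length(configs) >= 1, length(methods) >= 1)
  methods <- match.arg(methods, c("iterative", "lr", "ensemble"),
                       several.ok = TRUE)
  rows <- list()
  for (g in seq_along(configs)) {
    cfg <- configs[[g]]
    sc <- attr(cfg, "scenario") %||%
      list(class = NA_character_, snr = NA_character_, replicate = g)
    sim <- simulate_population(cfg)
    for (m in methods) {
      res <- tryCatch({
        pred <- switch(m,
          iterative = iterative_predict(sim$pla, it_settings),
          lr = lr_predict(sim$pla, sim$nonproximal, lr_settings),
          ensemble = ensemble_predict(sim$pla, sim$nonproximal,
                                      lr_settings, it_settings))
        prediction_score(sim$truth, pred, weights)
      }, error = function(e) e)
      failed <- inherits(res, "error")
      rows[[length(rows) + 1L]] <- data.frame(
        config = g, class = sc$class, snr = sc$snr,
        replicate = sc$replicate, method = m,
        sum_pearson = if (failed) NA_real_ else res$sum_pearson,
        sum_mean_deviation = if (failed) NA_real_ else
          res$sum_mean_deviation,
        sum_fp_rate = if (failed) NA_real_ else res$sum_fp_rate,
        score = if (failed) NA_real_ else res$score,
        error = if (failed) conditionMessage(res) else "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Aggregate benchmark scores per method (and scenario class)
#'
#' @param results a [run_benchmark()] table.
#' @param by grouping columns, default method only.
#' @return data.frame of per-group median and variance of the score and
#'   the number of failed runs.
#' @export
summarize_benchmark <- function(results, by = "method") {
  groups <- interaction(results[by], drop = TRUE)
  out <- lapply(levels(groups), function(g) {
    r <- results[groups == g, ]
    data.frame(r[1L, by, drop = FALSE],
               median_score = median(r$score, na.rm = TRUE),
               var_score = var(r$score, na.rm = TRUE),
               n_runs = nrow(r), n_failed = sum(is.na(r$score)),
               row.names = NULL)
  })
  do.call(rbind, out)
}
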