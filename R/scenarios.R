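#' Generate randomized benchmark scenarios
#'
#' Builds simulation configurations for the standard benchmark: four
#' biological scenario classes crossed with a high (complex:monomer
#' abundance 10:1) or low (1:10) signal-to-noise regime, each replicated
#' with independently sampled abundances.  Per replicate, monomer and
#' homodimer means are drawn from a uniform distribution on
#' `[0.5, 2] x base mean`, heterodimer means from a triangular
#' distribution on the same range with mode at the base mean, and the
#' complex means are then rescaled so that the total complex abundance is
#' exactly `ratio` times the total monomer probe-A abundance.
#'
#' Scenario classes (three-protein panel):
#' \describe{
#'   \item{only_heterodimer}{complexes 1:2 and 2:1 only.}
#'   \item{only_homodimer}{complexes 1:1 and 2:2 only.}
#'   \item{one_overabundant}{protein 1's monomer mean is 10x the base;
#'     complexes 2:3 and 3:2.}
#'   \item{multiple_dimers}{complexes 1:1, 1:2, 2:1 and 3:3.}
#' }
#'
#' @param classes scenario classes to include (see above).
#' @param snr signal-to-noise regimes, subset of `c("high", "low")`.
#' @param n_replicates replicates per class x regime cell.
#' @param base_monomer_mean base non-interacting probe mean (UMIs/cell).
#' @param n_cells cells per simulated population.
#' @param nb_dispersion,radius,ligation_distance forwarded to
#'   [sim_config()].
#' @param seed seed for both the samplers and the per-config simulation
#'   seeds.
#' @return list of `sim_config` objects; each carries a `scenario`
#'   attribute (class, snr, replicate).
#' @export
generate_scenarios <- function(classes = c("only_heterodimer",
                                           "only_homodimer",
                                           "one_overabundant",
                                           "multiple_dimers"),
                               snr = c("high", "low"),
                               n_replicates = 100L,
                               base_monomer_mean = 50,
                               n_cells = 100L,
                               nb_dispersion = 1.5,
                               radius = 5000,
                               ligation_distance = 50,
                               seed = 1L) {
  classes <- match.arg(classes, several.ok = TRUE)
  snr <- match.arg(snr, several.ok = TRUE)
  stopifnot(n_replicates >= 1)
  patterns <- list(
    only_heterodimer = cbind(c(1L, 2L), c(2L, 1L)),
    only_homodimer   = cbind(c(1L, 2L), c(1L, 2L)),
    one_overabundant = cbind(c(2L, 3L), c(3L, 2L)),
    multiple_dimers  = cbind(c(1L, 1L, 2L, 3L), c(1L, 2L, 1L, 3L)))
  set.seed(seed)
  configs <- list()
  for (cls in classes) for (s in snr) for (r in seq_len(n_replicates)) {
    ratio <- if (s == "high") 10 else 0.1
    monomer <- runif(3L, 0.5, 2) * base_monomer_mean
    if (cls == "one_overabundant") monomer[1L] <- monomer[1L] * 10
    pat <- patterns[[cls]]
    homo <- pat[, 1L] == pat[, 2L]
    w <- numeric(nrow(pat))
    w[homo] <- runif(sum(homo), 0.5, 2)
    w[!homo] <- rtriangular(sum(!homo), 0.5, 1, 2)
    cm <- matrix(0, 3L, 3L)
    cm[pat] <- w / sum(w) * ratio * sum(monomer)
    cfg <- sim_config(probe_a_means = monomer,
                      complex_means = cm,
                      nb_dispersion = nb_dispersion,
                      radius = radius,
                      ligation_distance = ligation_distance,
                      n_cells = n_cells,
                      seed = sample.int(2147483646L, 1L))
    attr(cfg, "scenario") <- list(class = cls, snr = s, replicate = r)
    configs[[length(configs) + 1L]] <- cfg
  }
  configs
}
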