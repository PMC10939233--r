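#' Probability that two random surface points are within ligation distance
#'
#' For two independent uniform points on a sphere of radius `R`, the chord
#' distance `L` has density `L / (2 R^2)` on `(0, 2R]`, so
#' `P(L <= d) = d^2 / (4 R^2)`.  This is the per-pair ligation probability
#' underlying the binomial proximity-noise approximation; no small-angle
#' correction is applied.
#'
#' @param d ligation distance, `0 < d <= 2R`.
#' @param radius cell radius R (> 0).
#' @return probability in (0, 1].
#' @examples
#' ligation_probability(50, 5000)   # 2.5e-5
#' @export
ligation_probability <- function(d, radius) {
  if (any(d <= 0) || any(radius <= 0)) stop("d and radius must be > 0")
  if (any(d > 2 * radius)) stop("d must be <= 2 * radius")
  d^2 / (4 * radius^2)
}

#' Expected random (proximity-noise) PLA count
#'
#' Under the binomial approximation, `A` probe-A and `B` probe-B points
#' yield `Binomial(A * B, d^2 / (4 R^2))` random ligations, with
#' expectation `d^2 / (4 R^2) * A * B`.  The approximation lets every probe
#' ligate any number of times, while the simulator ligates each probe at
#' most once, so this value is an upper bound on the simulated mean
#' no-complex PLA count.
#'
#' @param a,b probe-A and probe-B counts (>= 0).
#' @param d ligation distance.
#' @param radius cell radius.
#' @return expected random PLA UMI count.
#' @examples
#' expected_random_count(1000, 1000, 50, 5000)  # 25
#' @export
expected_random_count <- function(a, b, d, radius) {
  if (any(a < 0) || any(b < 0)) stop("a and b must be >= 0")
  ligation_probability(d, radius) * a * b
}

#' Monte-Carlo proximity-noise scaling curve
#'
#' Simulates a one-protein, no-complex population for every combination of
#' probe abundance (`A = B`) and ligation distance, and reports the mean
#' simulated PLA count with its standard error next to the closed-form
#' expectation.  A joint log-log fit
#' `log(mean) ~ log(abundance) + log(distance)` summarizes the scaling; the
#' noise grows quadratically in both, so both slopes are 2 up to
#' Monte-Carlo error.  Simulations use `variance_mode = "none"` so the
#' curve isolates the geometric matching noise.
#'
#' @param abundance_grid probe abundances (A = B) to scan.
#' @param distance_grid ligation distances to scan.
#' @param radius cell radius.
#' @param n_cells Monte-Carlo cells per grid point.
#' @param seed RNG seed.
#' @return data.frame with columns `abundance`, `distance`, `mean_count`,
#'   `se`, `expected`; the fitted slopes are in `attr(, "slopes")`.
#' @export
noise_scaling_curve <- function(abundance_grid, distance_grid, radius = 5000,
                                n_cells = 500, seed = 1L) {
  if (!length(abundance_grid) || !length(distance_grid))
    stop("grids must be non-empty")
  grid <- expand.grid(abundance = abundance_grid, distance = distance_grid)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    a <- grid$abundance[g]; d <- grid$distance[g]
    cfg <- sim_config(probe_a_means = a, complex_means = NULL,
                      radius = radius, ligation_distance = d,
                      n_cells = n_cells,
                      seed = cell_seed(seed, g * 1000L),
                      variance_mode = "none")
    x <- simulate_population(cfg)$pla[, 1L]
    c(mean = mean(x), se = sd(x) / sqrt(length(x)))
  })
  res <- do.call(rbind, res)
  out <- data.frame(grid, mean_count = res[, "mean"], se = res[, "se"],
                    expected = expected_random_count(grid$abundance,
                                                     grid$abundance,
                                                     grid$distance, radius))
  ok <- out$mean_count > 0
  slopes <- c(abundance = NA_real_, distance = NA_real_)
  if (sum(ok) >= 3) {
    fit <- lm(log(mean_count) ~ log(abundance) + log(distance),
              data = out[ok, ])
    slopes <- setNames(coef(fit)[-1L], c("abundance", "distance"))
  }
  attr(out, "slopes") <- slopes
  out
}
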