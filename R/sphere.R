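#' Sample uniform random points on a sphere surface
#'
#' Points are generated with the area-preserving parameterization
#' `x = R sqrt(1 - u^2) cos(theta)`, `y = R sqrt(1 - u^2) sin(theta)`,
#' `z = R u`, where `u ~ Uniform[-1, 1)` and `theta ~ Uniform[0, 2*pi)`,
#' which yields the uniform distribution on the sphere of radius `R`.
#'
#' Draws come from the R session RNG; seed it with [set.seed()] for
#' reproducibility.
#'
#' @param n number of points (>= 0).
#' @param radius sphere radius R (> 0).
#' @return numeric `n x 3` matrix of coordinates (columns x, y, z).
#' @examples
#' set.seed(1)
#' p <- sample_sphere_points(5, 5000)
#' sqrt(rowSums(p^2))  # all 5000
#' @export
sample_sphere_points <- function(n, radius) {
  if (length(n) != 1L || is.na(n) || n < 0) stop("n must be >= 0")
  if (length(radius) != 1L || !is.finite(radius) || radius <= 0)
    stop("radius must be > 0")
  n <- as.integer(n)
  if (n == 0L) return(matrix(numeric(0), 0L, 3L,
                             dimnames = list(NULL, c("x", "y", "z"))))
  u <- runif(n, -1, 1)
  theta <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - u^2)
  cbind(x = radius * s * cos(theta),
        y = radius * s * sin(theta),
        z = radius * u)
}

#' Draw negative binomial UMI counts with a target mean
#'
#' Counts are drawn as `NegativeBinomial(size = n_nb, p_nb)` with
#' `p_nb = (1 + mean/n_nb)^-1`, i.e. the number of failures before `n_nb`
#' successes; this parameterization has expectation `mean` and variance
#' `mean + mean^2 / n_nb`, so `n_nb` controls the overdispersion of the
#' simulated UMI counts.  A mean of 0 returns zeros.
#'
#' @param n number of draws.
#' @param mean target expected count (>= 0).
#' @param n_nb dispersion parameter `n_NB` (> 0); default 1.5.
#' @return integer vector of `n` non-negative counts.
#' @export
sample_nb_count <- function(n, mean, n_nb = 1.5) {
  if (length(mean) != 1L || is.na(mean) || mean < 0)
    stop("mean must be >= 0")
  if (length(n_nb) != 1L || !is.finite(n_nb) || n_nb <= 0)
    stop("n_nb must be > 0")
  if (mean == 0) return(integer(n))
  as.integer(rnbinom(n, size = n_nb, mu = mean))
}

# Inverse-CDF sampler for the triangular distribution on [min, max] with the
# given mode; used by the benchmark scenario generator.
rtriangular <- function(n, min, mode, max) {
  stopifnot(min <= mode, mode <= max, min < max)
  u <- runif(n)
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}
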